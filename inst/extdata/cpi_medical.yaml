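# Multipliers restating service-year US dollars in 2013 US dollars using
# the medical-care component of the Consumer Price Index. Placeholder
# approximations of the CPI-Medical ratios; replace with the official BLS
# series for production use. The reference year (2013) must be 1.0.
reference_year: 2013
factors:
  2009: 1.132
  2010: 1.095
  2011: 1.063
  2012: 1.026
  2013: 1.000
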