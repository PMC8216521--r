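# Mexico tobacco-control policy timeline, 2002-2018.
# Levels persist until changed (step functions keyed by calendar year).
# The price series is SYNTHETIC: the official real-price data are not
# public in tabulated form, so a deterministic stand-in path (+8%/year
# real over the 2003-2011 tax-reform era, flat thereafter) is bundled;
# replace it with observed prices for applied use.
name: mexico_2002_2018
baseline_year: 2002
nondaily_scale: 1.0
price_symmetric: true
price:
  2002: 30.0000
  2003: 32.4000
  2004: 34.9920
  2005: 37.7914
  2006: 40.8147
  2007: 44.0798
  2008: 47.6062
  2009: 51.4147
  2010: 55.5279
  2011: 59.9701
  2012: 59.9701
  2013: 59.9701
  2014: 59.9701
  2015: 59.9701
  2016: 59.9701
  2017: 59.9701
  2018: 59.9701
policies:
  health_warnings:
    level:
      2002: low
      2004: moderate
      2010: high
  smoke_free:
    enforcement: 4
    coverage:
      worksite:
        2002: 0.0
        2008: 0.10
        2010: 0.18
        2014: 0.45
      restaurant:
        2002: 0.0
        2010: 0.60
        2013: 0.70
      bar:
        2002: 0.0
        2010: 0.60
        2013: 0.70
      other:
        2002: 0.0
  media_campaign:
    level:
      2002: none
      2005: low
  marketing_restrictions:
    enforcement: 5
    mix:
      2002:
        minimal: 0.5
      2004:
        minimal: 1.0
      2009:
        moderate: 0.75
        minimal: 0.25
  cessation_treatment:
    pharmacotherapy:
      2002: 1.0
    financial_coverage:
      2002: 0.0
      2007: 0.5
    financial_publicity: low
    quitline:
      2002: none
      2008: low
    brief_index:
      2002: 0.2
  youth_access:
    level:
      2002: low
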