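# Example (synthetic) sanfu calendar for demonstrations and tests.
# These intervals have the mandated structure (toufu and mofu 10 days each,
# zhongfu 10 or 20 days, ordered, non-overlapping) but are NOT the
# historical sanfu dates; supply your own calendar for real analyses.
sanfu_calendar:
  2018:
    toufu: ["2018-07-17", "2018-07-26"]
    zhongfu: ["2018-07-27", "2018-08-15"]
    mofu: ["2018-08-16", "2018-08-25"]
  2019:
    toufu: ["2019-07-12", "2019-07-21"]
    zhongfu: ["2019-07-22", "2019-08-10"]
    mofu: ["2019-08-11", "2019-08-20"]
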