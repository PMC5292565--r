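# run the whole suite even when acceptance-level expectations fail
options(testthat.progress.max_fails = 100)
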