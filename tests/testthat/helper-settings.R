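# the acceptance file hosts deliberately red quantitative checks (see the
# decisions ledger); never let their failures truncate the rest of the suite
options(testthat.progress.max_fails = 1000)
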