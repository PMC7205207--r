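## shared fixtures, loaded once per test run
par_chains <- parentalChains()
panel <- variantPanel()
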