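# The depth-gradient verification fixture (353 synthetic genes, depths
# 1/5/10/20/50x) takes a few minutes; build it once per test run.
fixture_cache <- new.env(parent = emptyenv())

depth_fixture <- function() {
  if (is.null(fixture_cache$dg)) {
    fixture_cache$dg <- depth_gradient_experiment(
      depths = c(1, 5, 10, 20, 50), cfg = sim_config(seed = 20260922))
  }
  fixture_cache$dg
}
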