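# Shared, lazily built fixtures (computed once per test session).

.fixture_env <- new.env()

survey_fixture <- function() {
  if (is.null(.fixture_env$survey)) {
    .fixture_env$survey <- synthesize_survey(seed = 42)
  }
  .fixture_env$survey
}

pipeline_fixture <- function() {
  if (is.null(.fixture_env$pipeline)) {
    .fixture_env$pipeline <- suppressMessages(
      run_pipeline(survey_fixture()$genomes))
  }
  .fixture_env$pipeline
}
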