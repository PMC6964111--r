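# Shared small fixtures, built once per test run.

fixtureShape <- c(32L, 32L, 8L)

fixtureTemplate <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- makeTemplate(fixtureShape, nTracts = 2, seed = 1)
    tpl
  }
})

# covariate model with all randomness off (deterministic cohorts)
quietCovariates <- function(...) {
  covariateModel(subjectSd = 0, noiseSd = 0, ...)
}

# tiny two-site pair with a known multiplicative effect on site 1
fixturePair <- function(n = 6, magnitude = 0.1, seed = 5,
                        covariates = covariateModel()) {
  tpl <- fixtureTemplate()
  fld <- makeSiteEffect(fixtureShape, "multiplicative", magnitude, seed = seed)
  list(
    site1 = generateCohort(tpl, n, covariates, fld, seed = seed + 1,
                           site = "site1"),
    site2 = generateCohort(tpl, n, covariates, identityField(fixtureShape),
                           seed = seed + 2, site = "site2"),
    field = fld, template = tpl
  )
}

wmIdx <- function(tpl = fixtureTemplate()) which(wmMask(tpl) > 0)
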