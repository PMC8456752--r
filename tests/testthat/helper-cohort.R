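# shared fixture builders (everything generated in code)

# covariate models with identical male/female cells: no sex confounds
null_covariate_models <- function() {
  cm <- default_covariate_models()
  for (nm in names(cm)) {
    cm[[nm]]$mean["male", ] <- cm[[nm]]$mean["female", ]
    cm[[nm]]$sd["male", ] <- cm[[nm]]$sd["female", ]
  }
  cm
}

# fully identical covariate distributions (no sex, no condition structure)
flat_covariate_models <- function() {
  cm <- default_covariate_models()
  for (nm in names(cm)) {
    cm[[nm]]$mean[] <- mean(cm[[nm]]$mean)
    cm[[nm]]$sd[] <- mean(cm[[nm]]$sd)
  }
  cm
}

# the spec's confounded study cohort: sex-shifted ICV, condition-shifted
# motion (the package defaults), n subjects
confounded_cohort <- function(n = 2000, seed = 7) {
  generate_phenotypes(cohort_spec(n, seed = seed))
}

# small cohort with a class effect planted on a network's inner edges
planted_cohort <- function(n, network, condition = "rest", d = 2,
                           seed = 101) {
  spec <- cohort_spec(n, covariate_models = null_covariate_models(),
                      seed = seed,
                      effect_plan = list(effect_entry(network$nodes,
                                                      condition, d, 1:3)))
  ph <- generate_phenotypes(spec)
  list(spec = spec, phenotypes = ph,
       cohort = generate_connectomes(ph, spec))
}

# tiny member configuration for fast unit tests
tiny_member_config <- function(...) {
  member_config(n_filters = 8L, epochs = 3L, batch_size = 16L, ...)
}
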