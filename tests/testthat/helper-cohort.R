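# shared fixture builders (everything generated in code, no stored data)

dmp_design <- function(samples, contrast = c("CNF", "PNF")) {
  samples$group <- factor(samples$group, levels = contrast)
  model.matrix(~ group + age + sex, samples)
}

dmp_random <- function(samples) {
  list(slide = samples$slide_id, patient = samples$patient_id)
}

# minimal hand-built beta_matrix for filter-semantics tests
tiny_bm <- function(beta, detp = NULL) {
  beta <- as.matrix(beta)
  if (is.null(detp)) detp <- matrix(0.001, nrow(beta), ncol(beta))
  beta_matrix(beta, detp)
}
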