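# Shared builders for the test suite. Expected values tagged "frozen" were
# computed with an independent calculator (numpy / exact enumeration) before
# the corresponding implementation was written.

grid15 <- function() seq(0.1, 0.9, length.out = 15)

# Noiseless dataset generated from a model's closed form.
noiseless_data <- function(model, params, a_w = grid15()) {
  isotherm_data(a_w, evaluate_isotherm(model, params, a_w))
}

# 15-point recovery grid kept inside the region where the printed set
# yields positive moisture (some published chung-pfost fits cross zero
# near a_w ~ 0.15) and inside the model's own a_w domain.
recovery_grid <- function(model, params) {
  lo <- 0.1
  hi <- if (model == "gab") min(0.9, 0.98 / params[["B"]]) else 0.9
  if (evaluate_isotherm(model, params, lo) <= 0)
    lo <- inverse_aw(model, params, 0.5)  # start where M = 0.5 % d.b.
  seq(lo, hi, length.out = 15)
}

# A mixed composition used for generic component-model checks.
mixed_composition <- function(oil = 0) {
  composition(sugar = 0.2, ash = 0.05, fiber = 0.15, starch = 0.4,
              protein = 0.2, oil = oil, label = "mixed test material")
}

# Identifiable published parameter sets used for recovery properties.
# GAB sets with B outside the fitting bounds (or with B*a_w << 1, where
# only the product A*B*C is estimable) are not identifiable on this grid.
recovery_sets <- function() {
  herbs <- c("C. morifolium flower", "A. formosanus Hayata")
  out <- list()
  for (m in setdiff(model_names(), "gab"))
    for (p in herbs)
      for (tc in c(5, 45))
        out[[paste(m, p, tc)]] <- list(model = m, product = p,
                                       temperature_C = tc,
                                       params = published_params(p, m, tc))
  for (tc in c(35, 45))
    out[[paste("gab", tc)]] <- list(model = "gab",
                                    product = "A. formosanus Hayata",
                                    temperature_C = tc,
                                    params = published_params(
                                      "A. formosanus Hayata", "gab", tc))
  out
}
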