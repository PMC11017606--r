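# Builds the bundled synthetic log-quadratic coefficient schedule
# (inst/extdata/logquad_coefs_synthetic.csv) by fitting the log-quadratic
# model life-table form to a deterministic family of Gompertz-Makeham
# schedules spanning a wide range of child-mortality levels, with
# independent adult-mortality variation providing the k-loading.
# Run from the package root: Rscript data-raw/make_coefs.R

devtools::load_all(".", quiet = TRUE)

age <- age_grid_abridged(110)

make_family <- function(sex) {
  q5_grid <- exp(seq(log(0.0015), log(0.20), length.out = 24))
  sa_grid <- exp(seq(log(0.5), log(25), length.out = 7))
  comp <- ltcisim:::synth_mx_components(age, sex)
  mx_list <- list()
  for (q5 in q5_grid) {
    for (sa in sa_grid) {
      sc <- uniroot(function(s) {
        lt <- lifetable(ltcisim:::synth_mx_eval(comp, s, sa), age,
                        sex = sex)
        interval_prob(lt, 0, 5) - q5
      }, c(1e-8, 200), tol = 1e-13)$root
      mx_list[[length(mx_list) + 1L]] <-
        ltcisim:::synth_mx_eval(comp, sc, sa)
    }
  }
  fit_logquad_coefs(mx_list, age, sex)
}

coefs <- rbind(make_family("male"), make_family("female"))
out <- file.path("inst", "extdata", "logquad_coefs_synthetic.csv")
write.csv(format(coefs, digits = 10, trim = TRUE), out,
          row.names = FALSE, quote = FALSE)
cat("wrote", out, "\n")

# quick closure / monotonicity report
cf <- read_logquad_coefs(out)
for (s in c("male", "female")) {
  for (q5 in c(0.003, 0.01, 0.05, 0.15)) {
    lt <- loglq_lifetable(cf, q5, 0, sex = s)
    cat(sprintf("%s q5=%.3f closure rel err %.2e  e0=%.1f\n", s, q5,
                abs(interval_prob(lt, 0, 5) - q5) / q5, lt$ex[1]))
  }
  ks <- seq(-2, 2, 0.5)
  a45 <- sapply(ks, function(k)
    interval_prob(loglq_lifetable(cf, 0.01, k, sex = s), 15, 45))
  cat(s, "45q15 monotone in k:", all(diff(a45) > 0), "\n")
}
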