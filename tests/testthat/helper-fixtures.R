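# Shared fixtures, built in code at test time.

# quantize doubles to 32-bit float so Float32 round trips are bit-exact
as_float32 <- function(x) {
  readBin(writeBin(as.double(x), raw(), size = 4L), "double",
          n = length(x), size = 4L)
}

tiny_template <- function(seed = 42) {
  make_template(grid_dims = c(6, 6, 6), max_fixels_per_voxel = 3,
                fill = 0.6, seed = seed)
}

# a small tract matrix with a known two-batch structure
small_cohort_matrix <- function(n_per_batch = 45, n_tracts = 23,
                                shift = 0, scale = 1, seed = 1,
                                n_patients = 0, mu0 = 0.5, cv = 0.1) {
  set.seed(seed)
  n <- 2 * n_per_batch + n_patients
  batch <- c(rep(c("siteA", "siteB"), each = n_per_batch),
             rep("siteB", n_patients))
  group <- c(rep("control", 2 * n_per_batch), rep("patient", n_patients))
  ids <- sprintf("S%03d", seq_len(n))
  tracts <- standard_tracts()[seq_len(n_tracts), ]
  mu_t <- mu0 * exp(stats::rnorm(n_tracts, 0, 0.1))
  vals <- matrix(NA_real_, n_tracts, n)
  # one subject effect + one tract-noise block per subject, in subject
  # order, so the control draws do not depend on how many patients follow
  for (s in seq_len(n)) {
    x <- mu_t + stats::rnorm(1, 0, cv * mu0) +
      stats::rnorm(n_tracts, 0, 0.02)
    if (batch[s] == "siteB") x <- mu_t + shift + scale * (x - mu_t)
    vals[, s] <- x
  }
  tract_matrix(vals, tracts[, c("name", "hemisphere")],
               tibble::tibble(id = ids, group = group, batch = batch,
                              age = stats::runif(n, 18, 64)),
               stage = "raw")
}
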