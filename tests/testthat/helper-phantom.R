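# Small synthetic images used across tests.

# bright ellipse occupying the lower half of a noisy slice
lower_ellipse_slice <- function(seed, H = 64L, W = 64L, contrast = 2000,
                                noise = 15) {
  set.seed(seed)
  r <- matrix(seq_len(H), H, W)
  c_ <- matrix(seq_len(W), H, W, byrow = TRUE)
  img <- matrix(rnorm(H * W, sd = noise), H, W)
  inside <- ((r - 0.75 * H) / (0.32 * H))^2 +
    ((c_ - 0.5 * W) / (0.55 * W))^2 <= 1  # spills into both bottom corners
  img[inside] <- img[inside] + contrast
  img
}

# quick tabular cohort for selection / modeling tests: n0+n1 patients,
# p features of which the first k carry signal of the given effect size
tabular_cohort <- function(seed, n_per_class = 30L, p = 40L, k = 3L,
                           effect = 2, slices_per_patient = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  labels <- rep(c(0L, 1L), each = n_per_class)
  ids <- sprintf("T%03d", seq_len(n))
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    x <- matrix(rnorm(slices_per_patient * p), slices_per_patient, p)
    x[, seq_len(k)] <- x[, seq_len(k)] + effect * labels[i]
    x
  }))
  colnames(rows) <- sprintf("f%03d", seq_len(p))
  data.frame(patient_id = rep(ids, each = slices_per_patient),
             slice_index = rep(seq_len(slices_per_patient) - 1L, n),
             label = rep(labels, each = slices_per_patient),
             rows, check.names = FALSE)
}
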