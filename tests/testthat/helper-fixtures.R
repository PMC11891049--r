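# Shared fixtures, all generated in code.

# noiseless decay for a truth triple on a given scheme
make_decay <- function(f_p, D_p, D_t, scheme, S0 = 1) {
  voxel_decay(ivim_signal(ivim_params(f_p, D_p, D_t, S0), scheme$b_values),
              scheme)
}

# matrix of Rician-noised replicates of one clean decay
make_noisy_voxels <- function(n, f_p, D_p, D_t, scheme, snr, seed = 1,
                              S0 = 1) {
  clean <- ivim_signal(ivim_params(f_p, D_p, D_t, S0), scheme$b_values)
  sigma <- S0 / snr
  withr::with_seed(seed, {
    nb <- length(clean)
    n1 <- matrix(rnorm(n * nb, 0, sigma), n)
    n2 <- matrix(rnorm(n * nb, 0, sigma), n)
    sqrt((matrix(clean, n, nb, byrow = TRUE) + n1)^2 + n2^2)
  })
}

# small two-patients-per-cell study configuration
tiny_counts <- function(n_benign = 2L, n_malignant = 2L) {
  data.frame(site = rep(c("A", "B", "C"), each = 2),
             label = rep(c("benign", "malignant"), times = 3),
             n_patients = rep(c(n_benign, n_malignant), times = 3))
}

# hand-buildable feature table for the statistics modules
make_feature_table <- function(values_by_method, metric = "D_t_mean",
                               site = "C", labels = NULL) {
  n <- length(values_by_method[[1]])
  if (is.null(labels)) labels <- rep(c("benign", "malignant"), length.out = n)
  rows <- do.call(rbind, lapply(names(values_by_method), function(m) {
    data.frame(patient_id = sprintf("p%03d", seq_len(n)), site = site,
               label = labels, method = m, metric = metric,
               value = values_by_method[[m]], stringsAsFactors = FALSE)
  }))
  class(rows) <- c("feature_table", class(rows))
  rows
}

# brute-force AUC by pair enumeration (ties count 1/2)
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}
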