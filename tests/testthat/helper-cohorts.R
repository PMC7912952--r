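# Shared fixtures, built in code at test time.

# Small healthy cohort for fast fits.
small_healthy <- function(n = 300, seed = 11, ...) {
  generate_healthy(synthetic_config(n = n, seed = seed, ...))
}

# A cohort whose diameters follow the linear model exactly (no latent
# factor, no noise): diameter = b0 + ba*(age/89) + bb*(bsa/2.8) + bf*female.
# Useful as an interpolation oracle for the Z-score arm.
noise_free_cohort <- function(n = 120, seed = 3,
                              beta = c(b0 = 10, ba = 6, bb = 9, bf = -1.5)) {
  set.seed(seed)
  age <- runif(n, 5, 89)
  female <- rep_len(c(1, 0), n)
  height <- ifelse(female == 1, 160, 175) + rnorm(n, 0, 6)
  weight <- 22 * (height / 100)^2 + rnorm(n, 0, 4)
  bsa <- compute_bsa(weight, height)
  d <- beta["b0"] + beta["ba"] * (age / 89) + beta["bb"] * (bsa / 2.8) +
    beta["bf"] * female
  as_aorta_cohort(data.frame(
    subject_id = paste0("NF", seq_len(n)), age = age,
    sex = ifelse(female == 1, "F", "M"),
    height_cm = height, weight_kg = weight,
    aan_mm = d, sov_mm = d, sj_mm = d, paa_mm = d,
    group = "healthy"))
}

# Brute-force Mann-Whitney AUC: count positive-negative pairs, ties half.
auc_bruteforce <- function(label, score) {
  s1 <- score[label == 1]; s0 <- score[label == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s1) * length(s0))
}

# The training-cohort centroid of a Q ensemble, mapped back to a raw
# subject record (median normalized features inverted through the spec).
ensemble_center_record <- function(ensemble, cohort) {
  df <- as.data.frame(cohort)
  raw <- aortanorm:::build_feature_frame(df, ensemble$features,
                                         ensemble$age_policy)
  center <- raw[which.min(rowSums(scale(raw)^2)), , drop = FALSE]
  df[rownames(center), , drop = FALSE]
}
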