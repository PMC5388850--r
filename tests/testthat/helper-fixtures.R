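# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

default_pulse <- function() fixture("pulse", pulse_model())

# Homogeneous sample frame (16 x 10 mm, 40 lines) with given tissue truths.
hom_frame <- function(a_eff = 0, aac = 0, alpha = 1.0, seed = 11,
                      density = 30) {
  key <- paste("hom", a_eff, aac, alpha, seed, density, sep = "_")
  fixture(key, {
    ph <- make_scatterer_phantom(16, 10, density,
                                 effective_radius_um = a_eff,
                                 acoustic_concentration_db = aac,
                                 attenuation_slope_db_cm_mhz = alpha,
                                 seed = seed)
    simulate_rf_frame(ph, default_pulse(), 40, 0.25)
  })
}

reference_fixture <- function() {
  fixture("reference", simulate_reference_frame(default_pulse(), 40, 0.25,
                                                16, 10, seed = 91))
}

# full-width interior core mask (2-14 mm deep) on the standard frame grid
interior_core <- function(frame) {
  dz <- axial_spacing_mm(frame)
  m <- matrix(FALSE, nrow(frame$samples), ncol(frame$samples))
  m[round(2 / dz):round(14 / dz), ] <- TRUE
  roi_mask(m, "core")
}

band_fixture <- function() pulse_band_mhz(default_pulse())

# 3-sigma separated two-class cohort at the clinical 42/14 class sizes:
# each of p features carries a 3-sigma class-mean shift (an idealized
# optimal feature set)
separated_cohort <- function(seed = 1L, delta = 3, p = 6) {
  spec <- cohort_spec(42L, 14L,
                      feature_names = paste0("f", seq_len(p)),
                      mean_good = rep(delta, p),
                      mean_poor = rep(0, p),
                      covariance = diag(p), seed = seed)
  generate_feature_cohort(spec)
}

# cohort where only f1 is informative; the rest are pure noise
one_informative_cohort <- function(seed = 1L, delta = 3, p = 5) {
  spec <- cohort_spec(42L, 14L,
                      feature_names = paste0("f", seq_len(p)),
                      mean_good = c(delta, rep(0, p - 1)),
                      mean_poor = rep(0, p),
                      covariance = diag(p), seed = seed)
  generate_feature_cohort(spec)
}

# brute-force GLCM pair-count oracle: independent double loop over pixels
glcm_oracle <- function(q, G, offsets, symmetric = TRUE) {
  counts <- matrix(0, G, G)
  nr <- nrow(q); nc <- ncol(q)
  for (off in offsets) {
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
      a <- q[i, j]; b <- q[i2, j2]
      if (is.na(a) || is.na(b)) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

# O(n^2) AUC oracle: explicit positive-negative pair counting
auc_pair_oracle <- function(scores, labels, positive) {
  pos <- scores[as.character(labels) == positive]
  neg <- scores[as.character(labels) != positive]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}
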