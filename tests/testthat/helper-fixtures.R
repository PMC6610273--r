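# Shared fixtures and independent oracles. Expensive objects are computed
# once per test run and memoized here.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# Desk-scale phantom spec shared by most tests: 32 x 32 x 24 mm field at
# 0.5 mm isotropic spacing.
small_spec <- function(...) {
  phantom_spec(dim = c(64, 64, 48), spacing = c(0.5, 0.5, 0.5), ...)
}

sheaths <- function(...) {
  w <- stats::setNames(rep(0, 10), region_names())
  vals <- list(...)
  for (nm in names(vals)) w[nm] <- vals[[nm]]
  w
}

# One inflamed phantom (grade-2 flexor 2), its acquisitions and SRR volume.
fx_phantom <- function() fixture("phantom", {
  generate_phantom(small_spec(sheath_mm = sheaths(flexor_2 = 3), seed = 42))
})

# Study configuration used for the end-to-end correlation and parameter
# recovery checks: 30 co-registered phantoms spanning the three severity
# categories, stratified 5-per-category training split.
fx_study_cfg <- function() pipeline_config(
  registration = "identity",
  n_phantoms = 30, severity_mix = c(1, 1, 1) / 3, n_per_category = 5,
  n_atlas = 3, phantom_dim = c(64, 64, 48), phantom_spacing = c(0.5, 0.5, 0.5),
  srr_max_iter = 30, srr_tol = 1e-5, seed = 7L
)

fx_study <- function() fixture("study", {
  suppressWarnings(run_phantom_study(fx_study_cfg()))
})

# --- independent oracles ----------------------------------------------------

# Brute-force fuzzy C-means (c = 2, m = 2): plain fixed-point iteration from
# random restarts, run to a tight tolerance; returns the best solution by
# objective. Independent of the package implementation.
fcm2_bruteforce <- function(x, restarts = 100, tol = 1e-10, seed = 1) {
  best <- NULL
  set.seed(seed)
  for (k in seq_len(restarts)) {
    ctr <- sort(runif(2, min(x), max(x)))
    if (ctr[1] == ctr[2]) next
    for (it in 1:500) {
      d1 <- (x - ctr[1])^2
      d2 <- (x - ctr[2])^2
      u1 <- d2 / (d1 + d2)
      u1[d1 == 0] <- 1; u1[d2 == 0 & d1 > 0] <- 0
      u2 <- 1 - u1
      nc <- c(sum(u1^2 * x) / sum(u1^2), sum(u2^2 * x) / sum(u2^2))
      if (max(abs(nc - ctr)) < tol) { ctr <- nc; break }
      ctr <- nc
    }
    obj <- sum(u1^2 * d1 + u2^2 * d2)
    if (is.null(best) || obj < best$obj) best <- list(centers = sort(ctr), obj = obj)
  }
  best
}

# Textbook two-pass Pearson correlation.
pearson_twopass <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Brute-force per-slice bone gap: minimum pairwise in-plane distance between
# radius and ulna voxel centers, slice by slice.
bone_gap_bruteforce <- function(labels) {
  lab <- labels$labels; sp <- labels$spacing
  nz <- dim(lab)[3]
  gap <- rep(Inf, nz)
  for (z in seq_len(nz)) {
    rad <- which(lab[, , z] == 13L, arr.ind = TRUE)
    uln <- which(lab[, , z] == 14L, arr.ind = TRUE)
    if (!nrow(rad) || !nrow(uln)) next
    dx <- outer(rad[, 1], uln[, 1], `-`) * sp[1]
    dy <- outer(rad[, 2], uln[, 2], `-`) * sp[2]
    gap[z] <- sqrt(min(dx^2 + dy^2))
  }
  gap
}

# Wrap a bare probability array as the one-sided map object expected by
# tenosynovitis_fraction.
as_c2_map <- function(p) {
  structure(list(p = p, model = NULL, spacing = c(1, 1, 1)),
            class = "one_sided_c2")
}
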