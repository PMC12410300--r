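# Independent scalar/loop oracles used to cross-check the vectorized
# implementations, plus small fixture builders. All fixtures are generated
# in code under fixed seeds.

# closed-form OLS slope/SE t for a single voxel (independent of the
# vectorized path: plain textbook sums)
ols_t_oracle <- function(y, x) {
  n <- length(y)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  res <- y - (yb + slope * (x - xb))
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  if (se == 0) return(NA_real_)
  slope / se
}

# pooled-variance unpaired t for one voxel
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# stack-based flood fill over a binary 3-D array; returns an integer label
# array (0 outside). Deliberately naive: voxel-at-a-time neighbor walk.
flood_fill_oracle <- function(bin, connectivity) {
  d <- dim(bin)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ord <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = ord == 1, "18" = ord >= 1 & ord <= 2,
                    "26" = ord >= 1), , drop = FALSE]
  lab <- array(0L, d)
  nextlab <- 0L
  todo <- which(bin, arr.ind = TRUE)
  for (s in seq_len(nrow(todo))) {
    v <- todo[s, ]
    if (lab[v[1], v[2], v[3]] != 0L) next
    nextlab <- nextlab + 1L
    stack <- list(v)
    lab[v[1], v[2], v[3]] <- nextlab
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(off))) {
        nb <- cur + off[r, ]
        if (any(nb < 1L) || any(nb > d)) next
        if (bin[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nextlab
          stack[[length(stack) + 1L]] <- nb
        }
      }
    }
  }
  lab
}

# multiset of cluster voxel-sets from a flood-fill labeling, sizes > min_size
oracle_cluster_sets <- function(lab, min_size) {
  labs <- setdiff(unique(as.vector(lab)), 0L)
  out <- lapply(labs, function(l) sort(which(lab == l)))
  out <- out[vapply(out, length, 0L) > min_size]
  out[order(vapply(out, `[`, 0L, 1L))]
}

cluster_sets_from <- function(clusters, d) {
  out <- lapply(clusters, function(cl)
    sort(cl$voxels[, 1] + (cl$voxels[, 2] - 1L) * d[1] +
           (cl$voxels[, 3] - 1L) * d[1] * d[2]))
  out[order(vapply(out, `[`, 0L, 1L))]
}

# wrap a plain array as a t_map via the public constructor path
tmap_from_array <- function(arr, mask = NULL, dof = 10L) {
  d <- dim(arr)
  if (is.null(mask))
    mask <- volume(array(1L, d), 1, "label")
  vols <- list(volume(arr, 1, "Bq/mL"), volume(arr, 1, "Bq/mL"),
               volume(arr * 0, 1, "Bq/mL"), volume(arr * 0, 1, "Bq/mL"))
  tm <- two_sample_tmap(vols[1:2], vols[3:4], mask)
  tm$t$values <- arr
  tm$dof <- as.integer(dof)
  tm$zero_variance <- integer()
  tm
}

# small test cohort: random positive volumes as subject scans
random_scans <- function(n, d = c(8, 8, 8), seed = 1, spacing = 1,
                         group = "g", exvivo = NULL) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    subject_scan(sprintf("%s_%02d", group, i), group,
                 injected_dose_Bq = 1e6,
                 volume(array(stats::runif(prod(d), 0.5, 2), d), spacing, "Bq/mL"),
                 exvivo_blood_Bq_per_g = if (is.null(exvivo)) NA_real_ else exvivo[i]))
}

# small phantom cohort shared by several test files
tiny_atlas <- function() build_default_atlas(c(24, 24, 48), 0.8)

tiny_cohort <- function(n_per_group = 4, seed = 11, ...) {
  simulate_cohort(tiny_atlas(),
                  cohort_spec(n_per_group = n_per_group, seed = seed, ...))
}
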