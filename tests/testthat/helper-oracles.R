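# Independent oracles and hand-built fixtures used across the suite.

# average ranks computed by sorting (independent of base::rank)
oracle_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    below <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- below + (ties + 1) / 2
  }
  r
}

# Pearson correlation from raw sums (independent of stats::cor)
oracle_pearson <- function(a, b) {
  n <- length(a)
  sa <- sum(a); sb <- sum(b)
  num <- n * sum(a * b) - sa * sb
  den <- sqrt(n * sum(a^2) - sa^2) * sqrt(n * sum(b^2) - sb^2)
  num / den
}

# rank-then-Pearson Spearman oracle
oracle_spearman <- function(a, b) oracle_pearson(oracle_ranks(a), oracle_ranks(b))

# exhaustive k-medoids: minimum total distance-to-medoid cost over all
# C(n, k) medoid sets
oracle_pam_cost <- function(xy, k) {
  n <- nrow(xy)
  dm <- as.matrix(dist(xy))
  sets <- utils::combn(n, k)
  best <- Inf
  for (j in seq_len(ncol(sets))) {
    cost <- sum(apply(dm[, sets[, j], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# average silhouette width computed from first principles for a given
# assignment (singletons contribute 0)
oracle_avg_silhouette <- function(xy, assignment) {
  dm <- as.matrix(dist(xy))
  n <- nrow(xy)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assignment == assignment[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(dm[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(assignment), assignment[i]),
                    function(cl) mean(dm[i, assignment == cl]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# 4-item fixtures: two As on the left, two Bs on the right
fixture_sort_1 <- function() {
  sort_record("fx1", "demo", c("A1", "A2", "B1", "B2"),
              x = c(0, 0, 10, 10), y = c(0, 1, 0, 1),
              canvas_w = 20, canvas_h = 20)
}

fixture_sort_2 <- function() {
  sort_record("fx2", "demo", c("A1", "A2", "B1", "B2"),
              x = c(0, 0, 4, 9), y = c(0, 2, 0, 1),
              canvas_w = 20, canvas_h = 20)
}

fixture_category_of <- function() {
  setNames(c("A", "A", "B", "B"), c("A1", "A2", "B1", "B2"))
}

# apply a rigid motion + uniform scaling to a sort, re-fitting the canvas
transform_sort <- function(s, angle = 0, scale = 1, dx = 0, dy = 0, reflect = FALSE) {
  xy <- cbind(s$x, s$y)
  if (reflect) xy[, 1] <- -xy[, 1]
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  xy <- scale * (xy %*% rot)
  xy[, 1] <- xy[, 1] - min(xy[, 1]) + dx
  xy[, 2] <- xy[, 2] - min(xy[, 2]) + dy
  sort_record(s$participant_id, s$condition, s$item_ids, xy[, 1], xy[, 2],
              canvas_w = max(xy[, 1]) + 1, canvas_h = max(xy[, 2]) + 1,
              moved_all = s$moved_all)
}

# small gaussian-blob point set for clustering tests
make_blobs <- function(centers, n_per, sd, seed) {
  set.seed(seed)
  xy <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  xy
}
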