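# Independent oracles and small fixture builders shared across the suite.

# Connected components of the <= sqrt(2) lattice adjacency, via pairwise
# distances and igraph; independent of the package's key/BFS implementation.
cc_oracle <- function(coords, epsilon = sqrt(2)) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  d2 <- as.matrix(stats::dist(coords))^2
  adj <- d2 > 0 & d2 <= epsilon^2 + 1e-9
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# Two integer labelings agree up to renaming of the positive labels
# (0 = noise on both sides).
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!all((a == 0) == (b == 0))) return(FALSE)
  key_a <- match(a, unique(a[a != 0]))
  key_b <- match(b, unique(b[b != 0]))
  identical(key_a, key_b)
}

# Exhaustive-cut-point information gain oracle: plain recursion on explicit
# value/label vectors, entropies from tables, every cut point enumerated.
ig_oracle <- function(values, labels) {
  ent <- function(y) {
    p <- table(y) / length(y)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  mdl_accept <- function(y, yl, yr, gain) {
    n <- length(y)
    k <- length(unique(y)); kl <- length(unique(yl)); kr <- length(unique(yr))
    delta <- log2(3^k - 2) - (k * ent(y) - kl * ent(yl) - kr * ent(yr))
    gain > (log2(n - 1) + delta) / n
  }
  split_rec <- function(x, y) {
    n <- length(x)
    o <- order(x)
    x <- x[o]; y <- y[o]
    cuts <- which(x[-n] < x[-1])
    if (length(cuts) == 0 || ent(y) == 0) return(n * ent(y))
    gains <- sapply(cuts, function(i)
      ent(y) - (i * ent(y[1:i]) + (n - i) * ent(y[(i + 1):n])) / n)
    b <- cuts[which.max(gains)]
    if (!mdl_accept(y, y[1:b], y[(b + 1):length(y)], max(gains)))
      return(n * ent(y))
    split_rec(x[1:b], y[1:b]) + split_rec(x[(b + 1):n], y[(b + 1):n])
  }
  ent(labels) - split_rec(values, labels) / length(values)
}

# Minimal subject_matrix over a line of voxels.
make_sm <- function(values, labels = NULL, positive_class = NULL) {
  values <- as.matrix(values)
  if (is.null(labels))
    labels <- rep(c("control", "positive"), length.out = nrow(values))
  subject_matrix(values, cbind(seq_len(ncol(values)) - 1L, 0L, 0L),
                 labels, positive_class = positive_class)
}

# Cohort with one perfectly separating voxel among noise columns.
make_perfect_cohort <- function(n_per_class = 10, n_noise = 20, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * (n_noise + 1)), n)
  labels <- rep(c("control", "positive"), each = n_per_class)
  x[, 1] <- ifelse(labels == "positive", 1, -1) + rnorm(n, sd = 0.05)
  make_sm(x, labels, positive_class = "positive")
}

jaccard_coords <- function(a, b) {
  ka <- do.call(paste, as.data.frame(a))
  kb <- do.call(paste, as.data.frame(b))
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# Small SVM grid used wherever the full Cartesian grid would be overkill.
small_grid <- function() svm_param_grid(kernels = "linear",
                                        svm_types = "C_SVM")
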