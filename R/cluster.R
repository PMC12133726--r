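# Cluster-based permutation tests: bin-wise paired t-tests, clusters of
# adjacent same-sign supra-threshold bins (4-connectivity in the
# time-frequency grid, montage graph in electrode space), cluster mass =
# sum of t-values, null distribution of the maximum |mass| over random
# within-subject condition flips (sign flips of the paired differences).

# vectorized paired t for all sign-flip permutations at once.
# D: subjects x bins. S: perms x subjects (+/-1). Squares are flip-
# invariant, so the per-bin second moment is shared across permutations.
.flip_t <- function(D, S) {
  n <- nrow(D)
  ss <- colSums(D^2)
  M <- (S %*% D) / n                       # perm x bins means
  varr <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  varr[varr < .Machine$double.eps] <- Inf  # zero-variance bins: t = 0
  M / sqrt(varr / n)
}

# adjacency list (integer neighbours) for an nf x nt grid, 4-connectivity,
# column-major indexing (frequency fastest)
.grid_adj <- function(nf, nt) {
  idx <- seq_len(nf * nt)
  f <- (idx - 1L) %% nf + 1L
  t <- (idx - 1L) %/% nf + 1L
  lapply(idx, function(i) {
    nb <- integer(0)
    if (f[i] > 1L) nb <- c(nb, i - 1L)
    if (f[i] < nf) nb <- c(nb, i + 1L)
    if (t[i] > 1L) nb <- c(nb, i - nf)
    if (t[i] < nt) nb <- c(nb, i + nf)
    nb
  })
}

# adjacency list from an edge tibble over the given (ordered) labels
.edges_adj <- function(edges, labels) {
  i <- match(edges$from, labels)
  j <- match(edges$to, labels)
  if (anyNA(i) || anyNA(j))
    stop("adjacency references electrodes absent from the data")
  adj <- vector("list", length(labels))
  for (k in seq_along(i)) {
    adj[[i[k]]] <- c(adj[[i[k]]], j[k])
    adj[[j[k]]] <- c(adj[[j[k]]], i[k])
  }
  adj
}

# group supra-threshold bins into same-sign connected clusters (BFS over
# the supra set only); returns a list of integer index vectors
.sign_clusters <- function(tvals, supra, adj) {
  if (length(supra) == 0) return(list())
  pos <- tvals > 0
  unseen <- rep(FALSE, length(tvals))
  unseen[supra] <- TRUE
  out <- list()
  for (s in supra) {
    if (!unseen[s]) next
    comp <- integer(0)
    queue <- s
    unseen[s] <- FALSE
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, v)
      for (nb in adj[[v]]) {
        if (unseen[nb] && pos[nb] == pos[v]) {
          unseen[nb] <- FALSE
          queue <- c(queue, nb)
        }
      }
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

.max_cluster_mass <- function(tvals, tcrit, adj) {
  supra <- which(abs(tvals) > tcrit)
  cl <- .sign_clusters(tvals, supra, adj)
  if (length(cl) == 0) return(0)
  max(abs(vapply(cl, \(ix) sum(tvals[ix]), numeric(1))))
}

# shared permutation engine; A, B: subjects x bins
.cluster_perm <- function(A, B, adj, n_perm, alpha_form, alpha_cluster, seed) {
  stopifnot(nrow(A) == nrow(B), ncol(A) == ncol(B))
  n <- nrow(A)
  if (n < 2) stop("need at least 2 subjects")
  if (n_perm < 100) stop("n_perm must be at least 100")
  D <- A - B
  tcrit <- stats::qt(1 - alpha_form / 2, n - 1)
  t_obs <- drop(.flip_t(D, matrix(1, 1, n)))
  supra <- which(abs(t_obs) > tcrit)
  members <- .sign_clusters(t_obs, supra, adj)
  masses <- vapply(members, \(ix) sum(t_obs[ix]), numeric(1))

  S <- .local_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                                n_perm, n))
  Tp <- .flip_t(D, S)
  null <- vapply(seq_len(n_perm),
                 \(p) .max_cluster_mass(Tp[p, ], tcrit, adj), numeric(1))
  p_corr <- vapply(masses, \(m) (1 + sum(null >= abs(m))) / (n_perm + 1),
                   numeric(1))
  signif <- p_corr < alpha_cluster
  mean_diff <- colMeans(D)
  mask <- rep(0, ncol(D))
  for (k in which(signif)) mask[members[[k]]] <- mean_diff[members[[k]]]
  list(
    clusters = tibble::tibble(
      cluster = seq_along(masses),
      sign = ifelse(masses >= 0, "positive", "negative"),
      n_bins = lengths(members), mass = masses, p = p_corr,
      significant = signif
    ),
    members = members, null = null, t_map = t_obs, mask = mask,
    mean_diff = mean_diff,
    alpha_form = alpha_form, alpha_cluster = alpha_cluster,
    n_perm = n_perm, seed = seed
  )
}

#' Cluster-based permutation test on time-frequency maps
#'
#' Compares two conditions' per-subject ERSP maps: bin-wise paired
#' t-tests, clusters of 4-connected same-sign bins exceeding the forming
#' threshold, cluster mass = sum of t-values, and a null distribution of
#' maximum |mass| over `n_perm` random within-subject condition flips.
#' Clusters with corrected p below `alpha_cluster` are significant; the
#' returned `mask` holds the mean dB difference inside significant
#' clusters and zero elsewhere (the display rule for masked difference
#' maps).
#'
#' @param maps_a,maps_b Per-subject maps for the two conditions: lists of
#'   [ersp()] maps sharing axes (condition A minus condition B defines
#'   the difference sign), or subjects x freq x time arrays.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha_form Two-sided bin-forming threshold (default 0.05).
#' @param alpha_cluster Cluster-level significance threshold (default
#'   0.05).
#' @param seed Permutation RNG seed.
#' @param freq,time Axes (required when passing bare arrays).
#' @return A `cluster_result`: tibble of clusters (mass, corrected p,
#'   significance), member bins, the permutation null, the observed t
#'   map, and the masked difference map, each on the freq x time grid.
#' @export
cluster_perm_tf <- function(maps_a, maps_b, n_perm = 1000, alpha_form = 0.05,
                            alpha_cluster = 0.05, seed = 1,
                            freq = NULL, time = NULL) {
  unpack <- function(maps) {
    if (is.array(maps) && length(dim(maps)) == 3) return(maps)
    stopifnot(is.list(maps), length(maps) >= 2)
    f0 <- maps[[1]]$freq
    t0 <- maps[[1]]$time
    for (m in maps)
      if (!isTRUE(all.equal(m$freq, f0)) || !isTRUE(all.equal(m$time, t0)))
        stop("maps must share frequency and time axes")
    arr <- array(0, c(length(maps), length(f0), length(t0)))
    for (i in seq_along(maps)) arr[i, , ] <- maps[[i]]$values
    attr(arr, "freq") <- f0
    attr(arr, "time") <- t0
    arr
  }
  A <- unpack(maps_a)
  B <- unpack(maps_b)
  if (!all(dim(A) == dim(B))) stop("subject counts or axes differ")
  freq <- freq %||% attr(A, "freq") %||% seq_len(dim(A)[2])
  time <- time %||% attr(A, "time") %||% seq_len(dim(A)[3])
  nf <- dim(A)[2]
  nt <- dim(A)[3]
  adj <- .grid_adj(nf, nt)
  flat <- function(arr) matrix(arr, dim(arr)[1], nf * nt)
  res <- .cluster_perm(flat(A), flat(B), adj, n_perm, alpha_form,
                       alpha_cluster, seed)
  res$t_map <- matrix(res$t_map, nf, nt)
  res$mask <- matrix(res$mask, nf, nt)
  res$mean_diff <- matrix(res$mean_diff, nf, nt)
  res$freq <- freq
  res$time <- time
  res$space <- "time-frequency"
  class(res) <- "cluster_result"
  res
}

#' Cluster-based permutation test over electrodes
#'
#' As [cluster_perm_tf()], but clusters grow over the electrode
#' adjacency graph instead of the time-frequency grid.
#'
#' @param values_a,values_b Subjects x electrodes matrices (named
#'   columns) of per-subject scalars (e.g. mean AMI or ERD per
#'   electrode).
#' @param adjacency Edge tibble from [electrode_adjacency()]; must cover
#'   every data electrode.
#' @inheritParams cluster_perm_tf
#' @return A `cluster_result` with `electrodes` in place of the grid
#'   axes; `members` index into the electrode vector.
#' @export
cluster_perm_channels <- function(values_a, values_b,
                                  adjacency = electrode_adjacency(),
                                  n_perm = 1000, alpha_form = 0.05,
                                  alpha_cluster = 0.05, seed = 1) {
  A <- as.matrix(values_a)
  B <- as.matrix(values_b)
  if (is.null(colnames(A)) || is.null(colnames(B)))
    stop("electrode matrices need column names")
  if (!identical(colnames(A), colnames(B)))
    stop("electrode sets differ between conditions")
  labels <- colnames(A)
  missing_adj <- setdiff(labels, unique(c(adjacency$from, adjacency$to,
                                          attr(adjacency, "montage")$channel)))
  if (length(missing_adj) > 0)
    stop("electrode(s) absent from adjacency: ",
         paste(missing_adj, collapse = ", "))
  adj <- .edges_adj(adjacency[adjacency$from %in% labels &
                                adjacency$to %in% labels, ], labels)
  res <- .cluster_perm(A, B, adj, n_perm, alpha_form, alpha_cluster, seed)
  res$electrodes <- labels
  res$space <- "electrodes"
  class(res) <- "cluster_result"
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s space, %d permutations\n",
              x$space, x$n_perm))
  if (nrow(x$clusters) == 0) cat("no supra-threshold clusters\n")
  else print(x$clusters)
  invisible(x)
}
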