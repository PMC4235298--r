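# Independent brute-force oracles used to validate the closed-form metric
# implementations. They enumerate individuals explicitly and never share
# code with the package internals.

# Rao's Q by enumeration: expected dissimilarity between two individuals
# drawn with replacement (self-pairs included)
oracle_rao_q <- function(counts, d) {
  inds <- rep(names(counts), counts)
  mean(d[inds, inds])
}

# focal-species dispersion by enumeration of focal x non-focal individual
# pairs (abundance-weighted MPD)
oracle_qspec <- function(counts, focal, d, include_conspecifics = FALSE) {
  pool <- rep(names(counts), counts)
  others <- if (include_conspecifics) pool else pool[pool != focal]
  mean(d[focal, others])
}

# community-weighted mean by enumeration over individuals of species with
# measured trait values
oracle_cwm <- function(counts, trait_values) {
  inds <- rep(names(counts), counts)
  vals <- trait_values[inds]
  mean(vals[!is.na(vals)])
}

# cophenetic distances by explicit shortest-path sums over the tree graph
oracle_cophenetic <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  adj <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]
    b <- tree$edge[i, 2]
    len <- tree$edge.length[i]
    adj[[a]] <- rbind(adj[[a]], c(b, len))
    adj[[b]] <- rbind(adj[[b]], c(a, len))
  }
  dist_from <- function(start) {
    dist <- rep(NA_real_, n_node)
    dist[start] <- 0
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (j in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][j, 1]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + adj[[v]][j, 2]
          queue <- c(queue, u)
        }
      }
    }
    dist
  }
  out <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_tip)) {
    out[i, ] <- dist_from(i)[seq_len(n_tip)]
  }
  out
}

# random small community over the rows of a distance matrix
rand_counts <- function(d, k = NULL) {
  sp <- rownames(d)
  k <- k %||% sample(seq(1, min(8, length(sp))), 1)
  chosen <- sample(sp, k)
  setNames(sample(1:10, k, replace = TRUE), chosen)
}

# random symmetric distance matrix with zero diagonal
rand_dist <- function(n_sp) {
  m <- matrix(runif(n_sp^2, 0, 5), n_sp)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", seq_len(n_sp)), paste0("s", seq_len(n_sp)))
  m
}

# tiny community-matrix tibble from named count vectors (one per plot)
counts_to_comm <- function(...) {
  rows <- list(...)
  sp <- unique(unlist(lapply(rows, names)))
  out <- tibble::tibble(plot = paste0("p", seq_along(rows)))
  for (s in sp) {
    out[[s]] <- vapply(rows, function(r) {
      if (s %in% names(r)) as.numeric(r[[s]]) else 0
    }, numeric(1))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
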