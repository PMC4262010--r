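# Shannon-based weighted descriptors of quantitative bipartite webs.
# Entropies are computed in nats; effective numbers via exp(), so the
# logarithm base cancels. 0 * log(0) is treated as 0 throughout.

shannon_nats <- function(w) {
  w <- w[w > 0]
  if (length(w) == 0) return(0)
  p <- w / sum(w)
  -sum(p * log(p))
}

check_nonempty <- function(net) {
  stopifnot(inherits(net, "quantweb_network"))
  if (sum(net$a) <= 0) stop_not_applicable("metric undefined for an empty network")
}

#' Weighted generality, vulnerability, linkage density and connectance
#'
#' The marginal-weighted effective-number metrics for a quantitative
#' bipartite web. For parasitoid `j` with column total `A.j` out of a
#' matrix total `m`, its effective number of hosts is `exp(H_j)` where
#' `H_j` is the Shannon entropy of its column; generality is the mean of
#' these weighted by `A.j / m`. Vulnerability is the row-wise analogue
#' (effective parasitoids per host; unparasitised hosts carry zero
#' weight). Linkage density is the mean of generality and vulnerability,
#' and weighted connectance is linkage density divided by the total
#' species count `S = R + C`, with unparasitised hosts counted in `R`.
#'
#' @param net A [quantweb_network] with at least one interaction.
#' @return A single number.
#' @examples
#' net <- quantweb_network(matrix(c(2, 0, 1, 1), 2, 2))
#' generality(net)
#' vulnerability(net)
#' linkage_density(net)
#' weighted_connectance(net)
#' @export
generality <- function(net) {
  check_nonempty(net)
  a <- net$a
  cs <- colSums(a)
  keep <- cs > 0
  sum((cs[keep] / sum(a)) * exp(apply(a[, keep, drop = FALSE], 2, shannon_nats)))
}

#' @rdname generality
#' @export
vulnerability <- function(net) {
  check_nonempty(net)
  a <- net$a
  rs <- rowSums(a)
  keep <- rs > 0
  sum((rs[keep] / sum(a)) * exp(apply(a[keep, , drop = FALSE], 1, shannon_nats)))
}

#' @rdname generality
#' @export
linkage_density <- function(net) {
  (generality(net) + vulnerability(net)) / 2
}

#' @rdname generality
#' @export
weighted_connectance <- function(net) {
  linkage_density(net) / (nrow(net$a) + ncol(net$a))
}

#' Observed interaction entropy and its integer bounds
#'
#' `h2_observed()` returns the Shannon entropy (nats) of the interaction
#' proportions `p_ij = a_ij / m`. `h2_bounds()` returns, for an integer
#' network, the maximum and minimum entropy attainable by any integer
#' matrix with the same row and column marginal totals: the maximum is
#' found by largest-remainder rounding of the independence expectation
#' `r_i c_j / m` followed by marginal repair and entropy-increasing unit
#' moves along 2x2 cycles; the minimum by greedy packing (repeatedly
#' placing `min(remaining row, remaining column)` into the cell of the
#' currently largest marginals, ties broken towards the lowest index)
#' followed by entropy-decreasing cycle moves. Both are heuristics;
#' [h2_bounds_exact()] enumerates the true bounds for small matrices.
#'
#' @inheritParams generality
#' @return `h2_observed()`: entropy in nats. `h2_bounds()`: a list with
#'   `h2_obs`, `h2_min`, `h2_max`.
#' @examples
#' net <- quantweb_network(matrix(c(2, 0, 0, 2), 2, 2))
#' h2_observed(net)
#' h2_bounds(net)
#' @export
h2_observed <- function(net) {
  check_nonempty(net)
  shannon_nats(as.vector(net$a))
}

check_integer_net <- function(net, what) {
  if (!net$is_integer) {
    stop_not_applicable(sprintf(
      "%s requires integer interaction counts (network '%s' has non-integer cells)",
      what, net$network_id))
  }
}

# greedy most-concentrated packing given positive marginals; with
# exact_first = TRUE, placements where a remaining row total equals a
# remaining column total (a perfect fit, leaving no fragment) take
# priority, largest first
h2_min_matrix <- function(r, c, exact_first = FALSE) {
  A <- matrix(0, length(r), length(c))
  rr <- r
  cc <- c
  while (sum(rr) > 0) {
    placed <- FALSE
    if (exact_first) {
      match_val <- -Inf
      mi <- mj <- 0L
      for (i in which(rr > 0)) {
        j <- which(cc == rr[i])
        if (length(j) > 0 && rr[i] > match_val) {
          match_val <- rr[i]
          mi <- i
          mj <- j[1]
        }
      }
      if (mi > 0) {
        A[mi, mj] <- A[mi, mj] + match_val
        rr[mi] <- 0
        cc[mj] <- 0
        placed <- TRUE
      }
    }
    if (!placed) {
      i <- which.max(rr)
      j <- which.max(cc)
      v <- min(rr[i], cc[j])
      A[i, j] <- A[i, j] + v
      rr[i] <- rr[i] - v
      cc[j] <- cc[j] - v
    }
  }
  A
}

# reference R implementation of the independence rounding (the C++
# version h2_max_matrix_cpp is the one used; this stays as a slow
# readable counterpart for cross-checking)
h2_max_matrix <- function(r, c) {
  m <- sum(r)
  E <- outer(r, c) / m
  A <- floor(E)
  rem <- E - A
  short <- m - sum(A)
  if (short > 0) {
    ord <- order(-rem, row(E), col(E))
    A[ord[seq_len(short)]] <- A[ord[seq_len(short)]] + 1
  }
  f <- function(n) ifelse(n > 0, n * log(n), 0)
  # repair row totals by moving units within a column
  repeat {
    dr <- rowSums(A) - r
    if (all(dr == 0)) break
    over <- which(dr > 0)
    under <- which(dr < 0)
    best <- NULL
    best_delta <- Inf
    for (io in over) {
      js <- which(A[io, ] > 0)
      for (iu in under) {
        delta <- f(A[io, js] - 1) - f(A[io, js]) + f(A[iu, js] + 1) - f(A[iu, js])
        k <- which.min(delta)
        if (delta[k] < best_delta) {
          best_delta <- delta[k]
          best <- c(io, iu, js[k])
        }
      }
    }
    A[best[1], best[3]] <- A[best[1], best[3]] - 1
    A[best[2], best[3]] <- A[best[2], best[3]] + 1
  }
  # repair column totals by moving units within a row (rows stay fixed)
  repeat {
    dc <- colSums(A) - c
    if (all(dc == 0)) break
    over <- which(dc > 0)
    under <- which(dc < 0)
    best <- NULL
    best_delta <- Inf
    for (jo in over) {
      is <- which(A[, jo] > 0)
      for (ju in under) {
        delta <- f(A[is, jo] - 1) - f(A[is, jo]) + f(A[is, ju] + 1) - f(A[is, ju])
        k <- which.min(delta)
        if (delta[k] < best_delta) {
          best_delta <- delta[k]
          best <- c(is[k], jo, ju)
        }
      }
    }
    A[best[1], best[2]] <- A[best[1], best[2]] - 1
    A[best[1], best[3]] <- A[best[1], best[3]] + 1
  }
  A
}

#' @rdname h2_observed
#' @export
h2_bounds <- function(net) {
  check_nonempty(net)
  check_integer_net(net, "H2' entropy bounds")
  a <- round(net$a)
  r <- rowSums(a)
  c <- colSums(a)
  # bounds depend only on the marginal multisets; sorting makes the
  # heuristics exactly invariant to row/column permutation
  r <- sort(r[r > 0], decreasing = TRUE)
  c <- sort(c[c > 0], decreasing = TRUE)
  cands <- lapply(c(FALSE, TRUE), function(ef) {
    entropy_cycle_improve_cpp(h2_min_matrix(r, c, exact_first = ef),
                              FALSE, 100000L)
  })
  ents <- vapply(cands, function(A) shannon_nats(as.vector(A)), 0)
  Amin <- cands[[which.min(ents)]]
  Amax <- h2_max_matrix_cpp(r, c)
  Amax <- entropy_cycle_improve_cpp(Amax, TRUE, 100000L)
  list(h2_obs = shannon_nats(as.vector(a)),
       h2_min = shannon_nats(as.vector(Amin)),
       h2_max = shannon_nats(as.vector(Amax)))
}

#' Exact entropy bounds by exhaustive enumeration
#'
#' Enumerates every non-negative integer matrix with the given positive
#' row and column totals and returns the minimum and maximum Shannon
#' entropy. Intended as a test oracle for [h2_bounds()]; feasible only
#' for small totals (roughly `sum(r) <= 14` with dimensions up to 4x4).
#'
#' @param r,c Positive integer row and column marginal totals with
#'   `sum(r) == sum(c)`.
#' @return A list with `h2_min` and `h2_max` (nats).
#' @export
h2_bounds_exact <- function(r, c) {
  stopifnot(sum(r) == sum(c), all(r > 0), all(c > 0))
  if (sum(r) > 16 || length(r) > 4 || length(c) > 4) {
    stop_validation("exhaustive enumeration restricted to small matrices")
  }
  R <- length(r)
  C <- length(c)
  lims <- c(-Inf, Inf)  # running (max, min) via closure
  best <- c(Inf, -Inf)
  A <- matrix(0L, R, C)
  rec <- function(i, ccols) {
    if (i > R) {
      h <- shannon_nats(as.vector(A))
      if (h < best[1]) best[1] <<- h
      if (h > best[2]) best[2] <<- h
      return(invisible())
    }
    fill_row <- function(j, left) {
      if (j == C) {
        if (left <= ccols[C]) {
          A[i, C] <<- left
          rec(i + 1, ccols - A[i, ])
          A[i, C] <<- 0L
        }
        return(invisible())
      }
      for (v in 0:min(left, ccols[j])) {
        A[i, j] <<- v
        fill_row(j + 1, left - v)
      }
      A[i, j] <<- 0L
    }
    fill_row(1, r[i])
  }
  rec(1, c)
  list(h2_min = best[1], h2_max = best[2])
}

#' Network-level specialisation index H2'
#'
#' Scales the observed interaction entropy between the extremes
#' attainable under the network's fixed marginal totals:
#' `H2' = (H2max - H2obs) / (H2max - H2min)`. A value of 0 means the
#' interaction frequencies match the random (independence) expectation;
#' 1 means the web is as specialised as its marginals allow. Only
#' defined for integer count data. When the marginals leave no freedom
#' (`H2max == H2min`, e.g. a single cell) the index is 0 by convention.
#' The result is clipped to `[0, 1]` to absorb heuristic slack in the
#' bounds.
#'
#' @inheritParams generality
#' @return A number in `[0, 1]`.
#' @examples
#' h2_prime(quantweb_network(matrix(c(2, 0, 0, 2), 2, 2)))  # 1: fully specialised
#' h2_prime(quantweb_network(matrix(1, 2, 2)))              # 0: independence
#' @export
h2_prime <- function(net) {
  b <- h2_bounds(net)
  spread <- b$h2_max - b$h2_min
  if (spread <= 1e-12) return(0)
  min(1, max(0, (b$h2_max - b$h2_obs) / spread))
}

#' All network metrics for one network
#'
#' Assembles the six weighted descriptors into a one-row tibble. H2' is
#' `NA` for non-integer networks (the index is only defined for count
#' data); modularity is only computed when `include_modularity = TRUE`
#' since it requires stochastic optimisation.
#'
#' @inheritParams generality
#' @param include_modularity Compute weighted bipartite modularity via
#'   [optimise_modularity()]?
#' @param seed,chains Passed to [optimise_modularity()].
#' @return A one-row tibble with columns `network_id`, `study_id`,
#'   `latitude`, `guild`, `m`, `n_hosts`, `n_parasitoids`,
#'   `linkage_density`, `connectance`, `generality`, `vulnerability`,
#'   `h2prime`, `modularity`.
#' @export
compute_all_metrics <- function(net, include_modularity = FALSE,
                                seed = 1L, chains = 3L) {
  check_nonempty(net)
  g <- generality(net)
  v <- vulnerability(net)
  ld <- (g + v) / 2
  h2 <- if (net$is_integer) h2_prime(net) else NA_real_
  q <- if (include_modularity) {
    optimise_modularity(net, seed = seed, chains = chains)$q
  } else NA_real_
  tibble(network_id = net$network_id, study_id = net$study_id,
         latitude = net$latitude, guild = net$guild,
         m = matrix_size(net), n_hosts = n_hosts(net),
         n_parasitoids = n_parasitoids(net),
         linkage_density = ld,
         connectance = ld / (n_hosts(net) + n_parasitoids(net)),
         generality = g, vulnerability = v,
         h2prime = h2, modularity = q)
}

#' Metric table for a whole collection
#'
#' @param collection A [quantweb_collection].
#' @inheritParams compute_all_metrics
#' @return A tibble with one row per network (see
#'   [compute_all_metrics()]).
#' @export
network_metrics <- function(collection, include_modularity = FALSE,
                            seed = 1L, chains = 3L) {
  stopifnot(inherits(collection, "quantweb_collection"))
  purrr::list_rbind(purrr::imap(collection$network, function(net, i) {
    compute_all_metrics(net, include_modularity = include_modularity,
                        seed = seed + i, chains = chains)
  }))
}
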