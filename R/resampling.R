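# Rarefaction of interaction events: expand an integer web into its
# individual parasitism events, subsample without replacement, and
# summarise metrics across replicate subsamples.

# deterministic per-(network, size, replicate) seed from a master seed
hash_seed <- function(master, ...) {
  parts <- unlist(lapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(paste(x, collapse = "|"))) else as.numeric(x)
  }))
  v <- as.numeric(master) %% 2147483647
  for (p in parts) v <- (v * 69069 + p * 101 + 17) %% 2147483647
  as.integer(v %% 2147483646) + 1L
}

#' Expand an integer network into individual interaction events
#'
#' Returns the multiset of (host, parasitoid) parasitism events encoded
#' by the count matrix, in canonical row-major order: pair `(i, j)`
#' appears exactly `a_ij` times, so the list has length `m`.
#'
#' @inheritParams matrix_size
#' @return A tibble with columns `host` and `parasitoid`, one row per
#'   event.
#' @export
expand_events <- function(net) {
  stopifnot(inherits(net, "quantweb_network"))
  check_integer_net(net, "event expansion")
  a <- round(net$a)
  counts <- as.vector(t(a))  # row-major
  idx <- rep.int(seq_along(counts), counts)
  C <- ncol(a)
  tibble(host = rownames(a)[(idx - 1) %/% C + 1],
         parasitoid = colnames(a)[(idx - 1) %% C + 1])
}

# counts matrix after drawing n events without replacement
.subsample_counts <- function(a, n) {
  counts <- as.vector(a)
  events <- rep.int(seq_along(counts), counts)
  take <- sample(events, n, replace = FALSE)
  matrix(as.double(tabulate(take, nbins = length(counts))), nrow(a), ncol(a),
         dimnames = dimnames(a))
}

# skip validation when rebuilding a subsample of an already-valid network
fast_net <- function(template, a) {
  template$a <- a
  template
}

#' Randomly subsample interaction events from a network
#'
#' Draws `n` of the `m` individual parasitism events uniformly without
#' replacement and rebuilds the web. The full original host roster is
#' retained (hosts with no sampled events become all-zero rows,
#' consistent with keeping unparasitised hosts), whereas parasitoids
#' with no sampled events are dropped — a parasitoid exists in a
#' rearing-based web only through its events. Sampling all `m` events
#' returns a network identical to the original.
#'
#' @inheritParams matrix_size
#' @param n Number of events to draw, `1 <= n <= m`.
#' @param seed Integer seed making the draw reproducible; `NULL` uses
#'   the current RNG stream.
#' @return A [quantweb_network] whose cells sum to `n`.
#' @export
subsample <- function(net, n, seed = NULL) {
  stopifnot(inherits(net, "quantweb_network"))
  check_integer_net(net, "subsampling")
  a <- round(net$a)
  m <- sum(a)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n > m) {
    stop_validation(sprintf("subsample size must be in [1, m = %d]", m))
  }
  draw <- function() .subsample_counts(a, as.integer(n))
  sub <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  sub <- sub[, colSums(sub) > 0, drop = FALSE]
  out <- fast_net(net, sub)
  out$is_integer <- TRUE
  out
}

rarefaction_metric_names <- c("linkage_density", "connectance", "generality",
                              "vulnerability", "h2prime", "modularity")

# metric values for one (sub)network as a named vector; parasitoid
# columns with zero events are always dropped, and with
# hosts = "observed" zero rows are dropped too, so S counts only the
# species present in the subsample (this only affects connectance)
.metric_values <- function(template, a, include_modularity, seed, chains,
                           hosts = "observed") {
  a <- a[, colSums(a) > 0, drop = FALSE]
  if (hosts == "observed") a <- a[rowSums(a) > 0, , drop = FALSE]
  net <- fast_net(template, a)
  g <- generality(net)
  v <- vulnerability(net)
  ld <- (g + v) / 2
  out <- c(linkage_density = ld,
           connectance = ld / (nrow(a) + ncol(a)),
           generality = g, vulnerability = v,
           h2prime = h2_prime(net))
  if (include_modularity) {
    out <- c(out, modularity = optimise_modularity(net, seed = seed,
                                                   chains = chains)$q)
  }
  out
}

default_size_grid <- function(m, grid_points = 25L) {
  if (m < 2) stop_validation("rarefaction needs at least 2 events")
  sort(unique(pmin(m, pmax(2, round(exp(seq(log(2), log(m),
                                            length.out = grid_points)))))))
}

#' Rarefaction curve of network metrics
#'
#' For each target size, draws replicate random subsamples of that many
#' interaction events and averages each metric across replicates
#' (`reps` replicates, or `reps_modularity` for the stochastic
#' modularity score). The default size grid is geometric with at most
#' `grid_points` points between 2 and `m`; `sizes = "full"` uses every
#' integer from 2 to `m`. The endpoint `n = m` reproduces the original
#' metrics exactly.
#'
#' @inheritParams matrix_size
#' @param sizes Integer vector of target sizes in `[2, m]`, or `NULL`
#'   for the default geometric grid, or `"full"`.
#' @param reps Replicates per size for the deterministic metrics.
#' @param reps_modularity Replicates per size for modularity.
#' @param include_modularity Also rarefy modularity (slow)?
#' @param seed Master seed; per-(size, replicate) seeds are derived by
#'   hashing, so results are reproducible and order-independent.
#' @param chains Annealing restarts per modularity evaluation.
#' @param grid_points Number of points of the default geometric grid.
#' @param hosts `"observed"` (default): a subsampled web contains only
#'   the species its events touch, as when each subsample is written up
#'   as a network in its own right — only weighted connectance is
#'   sensitive to this. `"roster"`: keep every original host as a zero
#'   row (then the endpoint `n = m` reproduces the original connectance
#'   even for webs with unparasitised hosts).
#' @return A tibble of class `quantweb_rarefaction` with columns
#'   `network_id`, `study_id`, `size`, `metric`, `mean`, `reps`.
#' @export
rarefaction_curve <- function(net, sizes = NULL, reps = 100L,
                              reps_modularity = 50L,
                              include_modularity = FALSE, seed = 1L,
                              chains = 2L, grid_points = 25L,
                              hosts = c("observed", "roster")) {
  hosts <- match.arg(hosts)
  stopifnot(inherits(net, "quantweb_network"))
  check_integer_net(net, "rarefaction")
  a <- round(net$a)
  m <- sum(a)
  if (is.null(sizes)) {
    sizes <- default_size_grid(m, grid_points)
  } else if (identical(sizes, "full")) {
    sizes <- seq.int(2L, m)
  }
  sizes <- as.integer(sizes)
  if (any(sizes < 2 | sizes > m)) {
    stop_validation("rarefaction sizes must lie in [2, m]")
  }
  max_reps <- max(reps, if (include_modularity) reps_modularity else 0L)
  rows <- purrr::map(sizes, function(n) {
    acc <- matrix(NA_real_, max_reps, length(rarefaction_metric_names),
                  dimnames = list(NULL, rarefaction_metric_names))
    for (rep_i in seq_len(max_reps)) {
      s <- hash_seed(seed, net$network_id, n, rep_i)
      sub <- withr::with_seed(s, .subsample_counts(a, n))
      vals <- .metric_values(net, sub,
                             include_modularity && rep_i <= reps_modularity,
                             seed = s, chains = chains, hosts = hosts)
      acc[rep_i, names(vals)] <- vals
    }
    keep <- rarefaction_metric_names[c(rep(TRUE, 5), include_modularity)]
    reps_used <- c(rep(reps, 5), reps_modularity)[seq_along(keep)]
    tibble(network_id = net$network_id, study_id = net$study_id,
           size = n, metric = keep,
           mean = vapply(seq_along(keep), function(k) {
             mean(acc[seq_len(reps_used[k]), keep[k]])
           }, 0),
           reps = as.integer(reps_used))
  })
  out <- purrr::list_rbind(rows)
  attr(out, "seed") <- seed
  class(out) <- c("quantweb_rarefaction", class(out))
  out
}

#' Rarefaction curves for every integer network in a collection
#'
#' @param collection A [quantweb_collection]; non-integer networks are
#'   skipped with a warning.
#' @inheritParams rarefaction_curve
#' @return A combined `quantweb_rarefaction` tibble.
#' @export
collection_rarefaction <- function(collection, sizes = NULL, reps = 100L,
                                   reps_modularity = 50L,
                                   include_modularity = FALSE, seed = 1L,
                                   chains = 2L, grid_points = 25L,
                                   hosts = c("observed", "roster")) {
  hosts <- match.arg(hosts)
  stopifnot(inherits(collection, "quantweb_collection"))
  if (any(!collection$is_integer)) {
    warn(sprintf("skipping %d non-integer network(s)",
                 sum(!collection$is_integer)))
  }
  nets <- collection$network[collection$is_integer]
  out <- purrr::list_rbind(purrr::map(nets, rarefaction_curve, sizes = sizes,
                                      reps = reps,
                                      reps_modularity = reps_modularity,
                                      include_modularity = include_modularity,
                                      seed = seed, chains = chains,
                                      grid_points = grid_points,
                                      hosts = hosts))
  attr(out, "seed") <- seed
  class(out) <- c("quantweb_rarefaction", class(out))
  out
}

#' Tercile of the empirical matrix-size distribution
#'
#' Quantile of the distribution of `m` across the networks of a
#' collection at `which / 3`, using the empirical-distribution quantile
#' with linear interpolation (`type = 4`), under which the second
#' tercile of sizes {30, 65, 200} is 65.
#'
#' @param collection A [quantweb_collection] with at least 3 networks.
#' @param which Tercile number, 1 or 2.
#' @return A single size value.
#' @export
empirical_tercile <- function(collection, which = 2L) {
  stopifnot(inherits(collection, "quantweb_collection"))
  if (nrow(collection) < 3) stop_validation("need at least 3 networks")
  if (!which %in% c(1L, 2L)) stop_validation("`which` must be 1 or 2")
  unname(quantile(collection$m, which / 3, type = 4))
}

#' Standardise networks to a common matrix size
#'
#' Subsamples every eligible integer network down to `std_size` events
#' (default 65, the empirical second tercile of the compiled studies)
#' and reports the mean of each metric across replicates, together with
#' the original size for the follow-up regression of standardised
#' metrics on original size. Networks with `m < std_size` (or
#' non-integer data) are excluded and listed in the `excluded`
#' attribute. A network with `m == std_size` keeps its own metrics
#' exactly.
#'
#' @param collection A [quantweb_collection].
#' @param std_size Common target size (events).
#' @inheritParams rarefaction_curve
#' @return A tibble with columns `network_id`, `study_id`, `latitude`,
#'   `guild`, `m_original` and one column per metric mean, with
#'   attribute `excluded` (tibble of skipped networks and reasons).
#' @export
standardise_collection <- function(collection, std_size = 65L, reps = 100L,
                                   reps_modularity = 50L,
                                   include_modularity = FALSE, seed = 1L,
                                   chains = 2L, hosts = c("observed", "roster")) {
  hosts <- match.arg(hosts)
  stopifnot(inherits(collection, "quantweb_collection"))
  std_size <- as.integer(std_size)
  reason <- dplyr::case_when(
    !collection$is_integer ~ "non-integer data",
    collection$m < std_size ~ sprintf("m < %d", std_size),
    TRUE ~ NA_character_)
  excluded <- tibble(network_id = collection$network_id,
                     study_id = collection$study_id,
                     m = collection$m, reason = reason) |>
    dplyr::filter(!is.na(reason))
  eligible <- collection$network[is.na(reason)]
  if (length(eligible) == 0) {
    abort(sprintf("no network eligible for standardisation at size %d", std_size),
          class = c("quantweb_pipeline_error", "quantweb_error"))
  }
  rows <- purrr::map(eligible, function(net) {
    a <- round(net$a)
    max_reps <- max(reps, if (include_modularity) reps_modularity else 0L)
    acc <- matrix(NA_real_, max_reps, length(rarefaction_metric_names),
                  dimnames = list(NULL, rarefaction_metric_names))
    for (rep_i in seq_len(max_reps)) {
      s <- hash_seed(seed, net$network_id, std_size, rep_i)
      sub <- withr::with_seed(s, .subsample_counts(a, std_size))
      vals <- .metric_values(net, sub,
                             include_modularity && rep_i <= reps_modularity,
                             seed = s, chains = chains, hosts = hosts)
      acc[rep_i, names(vals)] <- vals
    }
    means <- c(
      colMeans(acc[seq_len(reps), 1:5, drop = FALSE]),
      modularity = if (include_modularity) {
        mean(acc[seq_len(reps_modularity), "modularity"])
      } else NA_real_)
    dplyr::bind_cols(
      tibble(network_id = net$network_id, study_id = net$study_id,
             latitude = net$latitude, guild = net$guild,
             m_original = sum(a)),
      as_tibble(as.list(means)))
  })
  out <- purrr::list_rbind(rows)
  attr(out, "excluded") <- excluded
  attr(out, "std_size") <- std_size
  attr(out, "seed") <- seed
  out
}
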