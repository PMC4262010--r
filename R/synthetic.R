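# uniform integer draw on [lo, hi] that never triggers sample()'s 1:n rule
rint <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else sample(seq(lo, hi), n, replace = TRUE)
}

# Synthetic multi-study generator: emulates a literature compilation of
# quantitative host-parasitoid webs (studies spread across latitudes and
# guilds, matrix sizes spanning orders of magnitude) with fully known
# ground truth, so every analysis stage can be exercised and calibrated
# without the original data.

#' Configuration for the synthetic collection generator
#'
#' Defaults emulate the compiled literature data the analyses are
#' designed for: 28 studies, five host guilds, latitudes from 34.6° S
#' to 74.5° N, and matrix sizes log-uniform over three orders of
#' magnitude. `theta` is the Dirichlet concentration of parasitoid host
#' preferences: small values give specialised parasitoids (high H2'),
#' large values unspecialised ones. Study-level heterogeneity enters as
#' Gaussian random effects on `log(theta)` (an intercept, and
#' optionally a slope on centred `log(m)`). Latitude and guild effects
#' are NOT built into the network mechanics; they are recorded in the
#' truth ledger and applied to the metric table afterwards via
#' [apply_injected_effects()], which keeps the injected truth exact.
#'
#' @param n_studies Number of studies.
#' @param networks_per_study Integer range (min, max) of networks drawn
#'   per study.
#' @param n_hosts,n_parasitoids Integer richness ranges per network.
#' @param size_range Range of matrix sizes `m`; sizes are drawn
#'   log-uniformly.
#' @param theta Baseline Dirichlet concentration of parasitoid
#'   preferences (> 0).
#' @param host_abundance_sd Lognormal sd of host availability weights.
#'   Rearing-based webs have strongly right-skewed abundances with many
#'   rarely-recorded species, so the default is well above 1.
#' @param parasitoid_abundance_sd Lognormal sd of parasitoid
#'   abundance/detectability weights; drives singleton parasitoids, so
#'   species keep accumulating with sampling effort as in real webs.
#' @param taxonomy_ranks Rank names, finest first (the first is the
#'   species assignment).
#' @param taxonomy_branching Integer children per parent at each rank
#'   transition (species per genus, genera per family, ...), plus the
#'   number of top-level taxa as the last element; the species pool has
#'   `prod(taxonomy_branching)` species.
#' @param study_sd_intercept,study_sd_slope Standard deviations of the
#'   study random effects on `log(theta)`.
#' @param tax_bias Strength of taxonomic clustering of parasitoid
#'   preferences (0 = off: a parasitoid's preferences ignore host
#'   taxonomy).
#' @param effect_latitude Named numeric vector of per-degree (absolute
#'   latitude) shifts injected into metric columns, e.g.
#'   `c(h2prime = 0.005)`.
#' @param effect_guild Named list mapping metric name to a named vector
#'   of per-guild offsets.
#' @param latitude_range Signed decimal degrees.
#' @param guilds Guild labels sampled per study.
#' @param seed Master seed; recorded in the output.
#' @return A list of class `quantweb_config`.
#' @export
generator_config <- function(n_studies = 28L,
                             networks_per_study = c(1L, 15L),
                             n_hosts = c(5L, 35L),
                             n_parasitoids = c(4L, 30L),
                             size_range = c(10, 1e4),
                             theta = 0.5,
                             host_abundance_sd = 2,
                             parasitoid_abundance_sd = 2,
                             taxonomy_ranks = c("species", "genus",
                                                "family", "order"),
                             taxonomy_branching = c(4L, 4L, 3L, 2L),
                             study_sd_intercept = 0.3,
                             study_sd_slope = 0,
                             tax_bias = 0,
                             effect_latitude = numeric(0),
                             effect_guild = list(),
                             latitude_range = c(-34.6, 74.5),
                             guilds = c("aphids", "gallers", "leaf chewers",
                                        "leaf miners", "trap nesters"),
                             seed = 1L) {
  stopifnot(n_studies >= 1, theta > 0, host_abundance_sd >= 0,
            length(size_range) == 2, size_range[1] >= 1,
            size_range[2] >= size_range[1],
            length(taxonomy_ranks) == length(taxonomy_branching),
            all(taxonomy_branching >= 1),
            networks_per_study[2] >= networks_per_study[1],
            n_hosts[2] >= n_hosts[1], n_parasitoids[2] >= n_parasitoids[1])
  structure(as.list(environment()), class = "quantweb_config")
}

#' Generate a nested random host taxonomy
#'
#' Builds a balanced classification tree from the branching factors in
#' the configuration (nesting is consistent by construction) and
#' assigns each host to a species: without replacement while hosts fit
#' in the species pool, with replacement otherwise (so a branching of 1
#' at every level makes all hosts conspecific).
#'
#' @param n_hosts Number of host labels to classify.
#' @param config A [generator_config()].
#' @param host_labels Optional host labels (default `h1..hn`).
#' @return A `quantweb_taxonomy` tibble.
#' @export
generate_taxonomy <- function(n_hosts, config = generator_config(),
                              host_labels = paste0("h", seq_len(n_hosts))) {
  br <- rev(as.integer(config$taxonomy_branching))  # top-level count first
  ranks <- rev(config$taxonomy_ranks)               # coarsest first
  n_taxa <- cumprod(br)
  paths <- matrix("", nrow = n_taxa[length(br)], ncol = length(br))
  idx <- seq_len(n_taxa[length(br)]) - 1L
  for (k in rev(seq_along(br))) {
    within <- idx %/% prod(br[seq_len(length(br))[-seq_len(k)]])
    paths[, k] <- sprintf("%s%d", substr(ranks[k], 1, 2), within + 1L)
  }
  n_species <- nrow(paths)
  sp <- sample.int(n_species, n_hosts, replace = n_hosts > n_species)
  df <- data.frame(host = host_labels,
                   paths[sp, rev(seq_along(br)), drop = FALSE],
                   stringsAsFactors = FALSE)
  names(df) <- c("host", config$taxonomy_ranks)
  taxonomy_table(df)
}

#' Generate one quantitative network
#'
#' Hosts get lognormal availability weights `w_i`; each parasitoid gets
#' a Dirichlet(`theta`) preference vector over hosts (optionally biased
#' towards a randomly chosen focal genus when `tax_bias > 0`); cell
#' probabilities are `p_ij` proportional to `w_i q_ij`, and the matrix
#' is a single multinomial draw of `m` events over the cells, so the
#' matrix size is exact. Hosts that attract no events are kept as
#' all-zero rows; parasitoids with no events are dropped.
#'
#' @param n_hosts,n_parasitoids Species numbers before the zero-column
#'   drop.
#' @param m Total number of interaction events.
#' @param theta Dirichlet concentration of parasitoid preferences.
#' @param config A [generator_config()] supplying abundance spread,
#'   taxonomy and clustering bias.
#' @param tax Optional `quantweb_taxonomy` for the hosts (required when
#'   `config$tax_bias > 0`).
#' @param host_labels Host labels (default `h1..hR`); must match the
#'   taxonomy when clustering is on.
#' @inheritParams quantweb_network
#' @return A [quantweb_network] with integer counts.
#' @export
generate_network <- function(n_hosts, n_parasitoids, m, theta,
                             config = generator_config(), tax = NULL,
                             network_id = "net1", study_id = "study1",
                             latitude = NA_real_, guild = NA_character_,
                             host_labels = paste0("h", seq_len(n_hosts))) {
  stopifnot(m >= 1, theta > 0, n_hosts >= 1, n_parasitoids >= 1,
            length(host_labels) == n_hosts)
  hosts <- host_labels
  w <- rlnorm(n_hosts, 0, config$host_abundance_sd)
  # Dirichlet(theta) preference per parasitoid, sampled in log space via
  # the shape boost log G = log Gamma(theta + 1) + log(U) / theta so that
  # tiny concentrations (near one-hot preferences) do not underflow
  lg <- log(rgamma(n_hosts * n_parasitoids, shape = theta + 1)) +
    log(runif(n_hosts * n_parasitoids)) / theta
  q <- matrix(lg, n_hosts, n_parasitoids)
  q <- apply(q, 2, function(v) {
    v <- exp(v - max(v))
    v / sum(v)
  })
  q <- matrix(q, n_hosts, n_parasitoids)
  v <- rlnorm(n_parasitoids, 0, config$parasitoid_abundance_sd)
  q <- sweep(q, 2, v, `*`)
  if (config$tax_bias > 0) {
    if (is.null(tax)) stop_validation("taxonomic clustering needs a taxonomy")
    genus_rank <- config$taxonomy_ranks[min(2, length(config$taxonomy_ranks))]
    genus <- setNames(tax[[genus_rank]], tax$host)[hosts]
    for (j in seq_len(n_parasitoids)) {
      focal <- genus[sample.int(n_hosts, 1)]
      q[genus == focal, j] <- q[genus == focal, j] * (1 + config$tax_bias)
    }
  }
  p <- w * q
  p <- p / sum(p)
  counts <- matrix(as.double(rmultinom(1, m, as.vector(p))),
                   n_hosts, n_parasitoids,
                   dimnames = list(hosts, paste0("p", seq_len(n_parasitoids))))
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  quantweb_network(counts, network_id = network_id, study_id = study_id,
                   latitude = latitude, guild = guild)
}

#' Generate a multi-study collection with a known-truth ledger
#'
#' Draws per-study latitudes, guilds and random effects, then per
#' network a matrix size (log-uniform), richness, and an interaction
#' matrix from [generate_network()] with
#' `log(theta) = log(config$theta) + b0_study + b1_study * centred log m`.
#' Everything is reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A list of class `quantweb_simulation` with elements
#'   `collection` (a [quantweb_collection]), `taxonomy` (a shared
#'   `quantweb_taxonomy` over the species pool), and `truth` (the
#'   ledger: per-study effects, per-network generating parameters, and
#'   the injected latitude/guild effects).
#' @export
generate_collection <- function(config = generator_config()) {
  stopifnot(inherits(config, "quantweb_config"))
  withr::with_seed(as.integer(config$seed), {
    pool <- prod(config$taxonomy_branching)
    tax <- generate_taxonomy(pool, config, host_labels = paste0("h", seq_len(pool)))
    # one host label per pool species so networks can share the taxonomy
    studies <- tibble(
      study_id = sprintf("S%02d", seq_len(config$n_studies)),
      latitude = runif(config$n_studies, config$latitude_range[1],
                       config$latitude_range[2]),
      guild = sample(config$guilds, config$n_studies, replace = TRUE),
      b0 = rnorm(config$n_studies, 0, config$study_sd_intercept),
      b1 = rnorm(config$n_studies, 0, config$study_sd_slope),
      n_networks = rint(config$networks_per_study[1],
                        config$networks_per_study[2], config$n_studies))
    mid_log_m <- mean(log(config$size_range))
    nets <- list()
    params <- list()
    for (s in seq_len(nrow(studies))) {
      for (k in seq_len(studies$n_networks[s])) {
        m <- round(exp(runif(1, log(config$size_range[1]),
                             log(config$size_range[2]))))
        R <- rint(config$n_hosts[1], config$n_hosts[2], 1)
        C <- rint(config$n_parasitoids[1], config$n_parasitoids[2], 1)
        theta_net <- exp(log(config$theta) + studies$b0[s] +
                           studies$b1[s] * (log(m) - mid_log_m))
        host_pool <- sample(tax$host, min(R, nrow(tax)))
        net_id <- sprintf("%s_n%02d", studies$study_id[s], k)
        net <- generate_network(length(host_pool), C, m, theta_net,
                                config = config,
                                tax = tax,
                                network_id = net_id,
                                study_id = studies$study_id[s],
                                latitude = studies$latitude[s],
                                guild = studies$guild[s],
                                host_labels = host_pool)
        nets[[length(nets) + 1L]] <- net
        params[[length(params) + 1L]] <- tibble(
          study_id = studies$study_id[s], network_id = net_id,
          m = m, n_hosts = length(host_pool), n_parasitoids = C,
          theta = theta_net)
      }
    }
    structure(list(
      collection = quantweb_collection(nets),
      taxonomy = tax,
      truth = list(studies = studies,
                   networks = purrr::list_rbind(params),
                   effect_latitude = config$effect_latitude,
                   effect_guild = config$effect_guild,
                   seed = config$seed)),
      class = "quantweb_simulation")
  })
}

#' Apply ledger-recorded latitude and guild effects to a metric table
#'
#' The generator records injected effects rather than distorting the
#' network mechanics, so recovery tests know the exact truth. This
#' helper shifts the named metric columns by
#' `beta * abs(latitude)` and by per-guild offsets.
#'
#' @param metrics A metric tibble (from [network_metrics()]) with
#'   `latitude` and `guild` columns.
#' @param truth The `truth` element of a `quantweb_simulation` (or a
#'   list with `effect_latitude` / `effect_guild`).
#' @return The shifted metric tibble.
#' @export
apply_injected_effects <- function(metrics, truth) {
  for (metric in names(truth$effect_latitude)) {
    metrics[[metric]] <- metrics[[metric]] +
      truth$effect_latitude[[metric]] * abs(metrics$latitude)
  }
  for (metric in names(truth$effect_guild)) {
    off <- truth$effect_guild[[metric]]
    metrics[[metric]] <- metrics[[metric]] +
      unname(off[metrics$guild])
  }
  metrics
}

#' Simulate a study-structured response on log matrix size
#'
#' Direct linear-mixed-model data generator used to calibrate the
#' inference machinery: `y = beta * log(m) + b_study + noise` with
#' `b_study ~ N(0, sd_study)` and log-uniform sizes. No networks are
#' built; this isolates the estimator from the metric pipeline.
#'
#' @param n_studies,networks_per_study Design dimensions.
#' @param beta True fixed slope on `log(m)`.
#' @param sd_study Study random-intercept sd.
#' @param sd_resid Residual sd.
#' @param size_range Matrix-size range (log-uniform draws).
#' @param seed Integer seed.
#' @return A tibble with `study_id`, `network_id`, `m`, `log_m`, `y`.
#' @export
simulate_size_response <- function(n_studies = 30L, networks_per_study = 5L,
                                   beta = 1, sd_study = 0.3, sd_resid = 0.3,
                                   size_range = c(10, 1e4), seed = 1L) {
  withr::with_seed(as.integer(seed), {
    study <- rep(sprintf("S%02d", seq_len(n_studies)), each = networks_per_study)
    b <- rep(rnorm(n_studies, 0, sd_study), each = networks_per_study)
    n <- length(study)
    m <- exp(runif(n, log(size_range[1]), log(size_range[2])))
    tibble(study_id = study,
           network_id = sprintf("%s_n%02d", study,
                                rep(seq_len(networks_per_study), n_studies)),
           m = m, log_m = log(m),
           y = beta * log(m) + b + rnorm(n, 0, sd_resid))
  })
}
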