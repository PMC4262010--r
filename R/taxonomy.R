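# Host taxonomic diversity: pairwise taxonomic distances with equal
# rank steps, and the abundance-weighted diversity index Delta.

#' Host taxonomy table
#'
#' Validates a hierarchical host classification. The first rank column
#' is the species assignment (distinct hosts may be conspecific); later
#' columns are successively coarser ranks. Nesting must be consistent:
#' two hosts sharing a value at any rank must share all coarser ranks.
#'
#' @param df A data frame with a `host` column and one column per rank,
#'   ordered from finest (species) to coarsest.
#' @param ranks Character vector naming the rank columns, finest first.
#'   Defaults to every non-`host` column in order.
#' @return A tibble of class `quantweb_taxonomy`.
#' @examples
#' tax <- taxonomy_table(data.frame(
#'   host = c("h1", "h2", "h3"),
#'   species = c("s1", "s2", "s3"),
#'   genus = c("gA", "gA", "gB"),
#'   family = c("fF", "fF", "fF")))
#' @export
taxonomy_table <- function(df, ranks = setdiff(names(df), "host")) {
  if (!"host" %in% names(df)) stop_malformed("taxonomy needs a `host` column")
  if (length(ranks) < 1) stop_malformed("taxonomy needs at least one rank column")
  if (!all(ranks %in% names(df))) stop_malformed("missing rank column(s)")
  if (anyDuplicated(df$host)) stop_validation("each host may appear only once")
  tab <- as_tibble(df[c("host", ranks)])
  tab[] <- lapply(tab, as.character)
  # consistent nesting: a value at rank k determines the value at rank k+1
  for (k in seq_len(length(ranks) - 1)) {
    fine <- tab[[ranks[k]]]
    coarse <- tab[[ranks[k + 1]]]
    n_parent <- tapply(coarse, fine, function(v) length(unique(v)))
    if (any(n_parent > 1)) {
      bad <- names(n_parent)[n_parent > 1][1]
      stop_validation(sprintf(
        "inconsistent nesting: %s '%s' maps to several %s values",
        ranks[k], bad, ranks[k + 1]))
    }
  }
  attr(tab, "ranks") <- ranks
  class(tab) <- c("quantweb_taxonomy", class(tab))
  tab
}

#' Read a host taxonomy file
#'
#' @param path CSV/TSV with header `host,<rank1>,<rank2>,...`, ranks
#'   ordered from finest (species) to coarsest.
#' @param delim Field delimiter; inferred from the extension when `NULL`.
#' @return A `quantweb_taxonomy` tibble.
#' @export
read_taxonomy <- function(path, delim = NULL) {
  delim <- infer_delim(path, delim)
  taxonomy_table(read.delim(path, sep = delim, stringsAsFactors = FALSE))
}

#' Pairwise taxonomic distances between hosts
#'
#' Path distances through the classification with equal step lengths
#' per rank, linearly scaled so that the maximum possible distance
#' (sharing no rank below the root) is 100. Conspecific hosts are at
#' distance 0. With `prune = TRUE` (the default, mirroring the
#' conventional equal-step implementation) ranks that carry no
#' information — a single value across all species, or one value per
#' species — are dropped before distances are computed, so the step
#' count runs over informative levels only.
#'
#' @param tax A `quantweb_taxonomy` (or data frame accepted by
#'   [taxonomy_table()]).
#' @param prune Drop uninformative rank columns before computing steps?
#' @return A symmetric numeric matrix with host labels as dimnames.
#' @examples
#' tax <- taxonomy_table(data.frame(
#'   host = c("h1", "h2", "h3"), species = c("s1", "s2", "s3"),
#'   genus = c("gA", "gA", "gB"), family = c("fF", "fF", "fF")))
#' taxonomic_distances(tax)  # congeners at 50, cross-genus at 100
#' @export
taxonomic_distances <- function(tax, prune = TRUE) {
  if (!inherits(tax, "quantweb_taxonomy")) tax <- taxonomy_table(tax)
  ranks <- attr(tax, "ranks")
  hosts <- tax$host
  species <- tax[[ranks[1]]]
  # classification at species level for ranks above species
  upper <- ranks[-1]
  sp_tab <- unique(tax[c(ranks)])
  S <- nrow(sp_tab)
  keep <- character(0)
  for (rk in upper) {
    u <- length(unique(sp_tab[[rk]]))
    if (!prune || (u > 1 && u < S)) keep <- c(keep, rk)
  }
  n <- length(hosts)
  steps <- matrix(0, n, n, dimnames = list(hosts, hosts))
  diff_at <- function(rk) outer(tax[[rk]], tax[[rk]], `!=`)
  distinct_sp <- outer(species, species, `!=`)
  steps <- steps + distinct_sp
  for (rk in keep) steps <- steps + (diff_at(rk) & distinct_sp)
  max_steps <- 1 + length(keep)
  100 * steps / max_steps
}

#' Taxonomic diversity index Delta of the hosts in a network
#'
#' The abundance-weighted mean taxonomic distance between pairs of
#' individuals of different host species:
#' `Delta = sum_{i<j} w_ij x_i x_j / (N (N - 1) / 2)` with `N = sum(x)`.
#' With `abundance = "host_marginals"` (default) `x_i` is host `i`'s
#' marginal total in the interaction matrix (unparasitised hosts then
#' carry zero weight); with `abundance = "presence"` every host counts
#' once. Distances `w_ij` come from [taxonomic_distances()], so Delta
#' runs from 0 (all individuals conspecific) to 100 (all pairs
#' maximally distant).
#'
#' @inheritParams modularity_score
#' @param tax A `quantweb_taxonomy` covering every host of the network.
#' @param abundance `"host_marginals"` or `"presence"`.
#' @param prune Passed to [taxonomic_distances()].
#' @return A one-row tibble with `network_id`, `delta`, `n_hosts`,
#'   `total_abundance`.
#' @export
delta_diversity <- function(net, tax,
                            abundance = c("host_marginals", "presence"),
                            prune = TRUE) {
  stopifnot(inherits(net, "quantweb_network"))
  abundance <- match.arg(abundance)
  if (!inherits(tax, "quantweb_taxonomy")) tax <- taxonomy_table(tax)
  hosts <- rownames(net$a)
  missing <- setdiff(hosts, tax$host)
  if (length(missing) > 0) {
    stop_validation(sprintf("host(s) not classified: %s",
                            paste(head(missing, 5), collapse = ", ")))
  }
  w <- taxonomic_distances(tax, prune = prune)[hosts, hosts, drop = FALSE]
  x <- if (abundance == "presence") rep(1, length(hosts)) else rowSums(net$a)
  N <- sum(x)
  if (N <= 1) {
    stop_not_applicable("Delta undefined: total host abundance must exceed 1")
  }
  num <- as.numeric(t(x) %*% w %*% x) / 2  # w has zero diagonal
  tibble(network_id = net$network_id,
         delta = num / (N * (N - 1) / 2),
         n_hosts = length(hosts), total_abundance = N)
}

#' Delta for every network of a collection
#'
#' @param collection A [quantweb_collection].
#' @inheritParams delta_diversity
#' @return A tibble with one row per network.
#' @export
collection_delta <- function(collection, tax,
                             abundance = c("host_marginals", "presence"),
                             prune = TRUE) {
  stopifnot(inherits(collection, "quantweb_collection"))
  abundance <- match.arg(abundance)
  purrr::list_rbind(purrr::map(collection$network, delta_diversity, tax = tax,
                               abundance = abundance, prune = prune))
}
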