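#' @useDynLib quantweb, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats quantile rnorm rgamma rmultinom runif rlnorm pchisq
#'   logLik AIC residuals coef setNames reformulate as.formula terms
#'   drop.scope update.formula sd aggregate predict model.response
#'   model.frame
#' @importFrom utils head read.delim write.table
"_PACKAGE"

stop_validation <- function(msg) {
  abort(msg, class = c("quantweb_validation_error", "quantweb_error"))
}
stop_malformed <- function(msg) {
  abort(msg, class = c("quantweb_malformed_error", "quantweb_error"))
}
stop_not_applicable <- function(msg) {
  abort(msg, class = c("quantweb_not_applicable_error", "quantweb_error"))
}

#' Quantitative bipartite interaction network
#'
#' Constructs a quantitative host-parasitoid network from a non-negative
#' interaction matrix. Rows are host species, columns are parasitoid
#' species, and each cell holds the number (or rate) of interaction
#' events recorded between the pair. Hosts that were sampled but never
#' parasitised are kept as all-zero rows, so that the species count used
#' by weighted connectance reflects the full host roster. All-zero
#' parasitoid columns are rejected: a parasitoid can only enter a
#' rearing-based web through at least one reared interaction.
#'
#' @param a Numeric matrix of non-negative interaction weights with
#'   hosts as rows and parasitoids as columns. Dimnames are used as
#'   species labels; unlabelled matrices get `h1..hR` / `p1..pC`.
#' @param network_id,study_id Identifiers; networks are grouped into
#'   studies for the random-effect structure of all mixed models.
#' @param latitude Signed decimal degrees of the study location
#'   (negative = southern hemisphere). Models use `abs(latitude)`.
#' @param guild Host feeding guild label (e.g. `"aphids"`, `"gallers"`,
#'   `"leaf chewers"`, `"leaf miners"`, `"trap nesters"`).
#'
#' @return An object of class `quantweb_network`: a list with elements
#'   `a` (the matrix), `network_id`, `study_id`, `latitude`, `guild` and
#'   `is_integer` (TRUE when every cell is integral, which decides H2'
#'   eligibility and subsampling eligibility).
#' @examples
#' net <- quantweb_network(matrix(c(2, 0, 0, 2), 2, 2))
#' matrix_size(net)
#' @export
quantweb_network <- function(a, network_id = "net1", study_id = "study1",
                             latitude = NA_real_, guild = NA_character_) {
  if (!is.matrix(a) || !is.numeric(a)) {
    stop_malformed("`a` must be a numeric matrix")
  }
  if (nrow(a) < 1L || ncol(a) < 1L) stop_validation("matrix must be at least 1x1")
  if (anyNA(a)) stop_malformed("interaction matrix contains missing values")
  if (is.null(rownames(a))) rownames(a) <- paste0("h", seq_len(nrow(a)))
  if (is.null(colnames(a))) colnames(a) <- paste0("p", seq_len(ncol(a)))
  neg <- which(a < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop_malformed(sprintf(
      "negative interaction weight at host '%s', parasitoid '%s'",
      rownames(a)[neg[1, 1]], colnames(a)[neg[1, 2]]))
  }
  if (sum(a) <= 0) stop_validation("network has no interactions (all cells zero)")
  zero_col <- colSums(a) == 0
  if (any(zero_col)) {
    stop_validation(sprintf(
      "all-zero parasitoid column(s): %s (a parasitoid cannot be recorded without an interaction)",
      paste(colnames(a)[zero_col], collapse = ", ")))
  }
  if (anyDuplicated(rownames(a))) stop_validation("duplicate host labels")
  if (anyDuplicated(colnames(a))) stop_validation("duplicate parasitoid labels")
  storage <- a
  if (is.integer(a)) {
    is_int <- TRUE
    storage[] <- as.double(a)
  } else {
    is_int <- all(abs(a - round(a)) <= 1e-9 * pmax(1, abs(a)))
  }
  structure(
    list(a = storage, network_id = as.character(network_id),
         study_id = as.character(study_id),
         latitude = as.double(latitude), guild = as.character(guild),
         is_integer = is_int),
    class = "quantweb_network")
}

#' @export
print.quantweb_network <- function(x, ...) {
  cat(sprintf(
    "<quantweb_network> %s (study %s): %d hosts x %d parasitoids, m = %s%s\n",
    x$network_id, x$study_id, nrow(x$a), ncol(x$a),
    format(matrix_size(x)), if (x$is_integer) " (integer counts)" else ""))
  invisible(x)
}

#' @export
as_tibble.quantweb_network <- function(x, ...) {
  idx <- which(x$a > 0, arr.ind = TRUE)
  tibble(network_id = x$network_id, study_id = x$study_id,
         host = rownames(x$a)[idx[, 1]],
         parasitoid = colnames(x$a)[idx[, 2]],
         weight = x$a[idx])
}

#' Total number of interaction events ("matrix size")
#'
#' The sum of all cells of the interaction matrix, i.e. the total number
#' of individual parasitism events documented in the web. Used as the
#' sampling-effort covariate throughout the size-correction analyses.
#'
#' @param net A [quantweb_network].
#' @return A single non-negative number.
#' @export
matrix_size <- function(net) {
  stopifnot(inherits(net, "quantweb_network"))
  sum(net$a)
}

#' @rdname matrix_size
#' @export
n_hosts <- function(net) nrow(net$a)

#' @rdname matrix_size
#' @export
n_parasitoids <- function(net) ncol(net$a)

infer_delim <- function(path, delim) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a quantitative network from a matrix file
#'
#' Reads a delimited interaction matrix whose first row holds parasitoid
#' labels and whose first column holds host labels. All-zero host rows
#' are preserved (hosts present but not parasitised); all-zero
#' parasitoid columns and negative cells are rejected.
#'
#' @param path Path to a CSV (comma) or TSV (tab) file.
#' @param delim Field delimiter; inferred from the extension when `NULL`.
#' @inheritParams quantweb_network
#' @return A [quantweb_network].
#' @export
read_network_matrix <- function(path, network_id = "net1", study_id = "study1",
                                latitude = NA_real_, guild = NA_character_,
                                delim = NULL) {
  delim <- infer_delim(path, delim)
  df <- read.delim(path, sep = delim, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_malformed("matrix file needs host labels plus at least one parasitoid column")
  if (anyDuplicated(names(df)[-1])) stop_validation("duplicate parasitoid labels")
  hosts <- as.character(df[[1]])
  if (anyDuplicated(hosts)) stop_validation("duplicate host labels")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop_malformed("non-numeric interaction cells in matrix file")
  rownames(mat) <- hosts
  quantweb_network(mat, network_id = network_id, study_id = study_id,
                   latitude = latitude, guild = guild)
}

#' Read a quantitative network from a long-format edge list
#'
#' Expects columns `host`, `parasitoid`, `weight`. Duplicate
#' (host, parasitoid) rows are summed. An optional host roster declares
#' hosts that were sampled but yielded no parasitoids; these become
#' all-zero rows. Host and parasitoid order follows first appearance
#' (roster first), so an edge list written from a matrix reads back to
#' the identical network.
#'
#' @param path Path to a delimited file with header `host,parasitoid,weight`.
#' @param roster Optional character vector of host labels, or path to a
#'   text file with one host label per line.
#' @inheritParams read_network_matrix
#' @return A [quantweb_network].
#' @export
read_edge_list <- function(path, network_id = "net1", study_id = "study1",
                           latitude = NA_real_, guild = NA_character_,
                           roster = NULL, delim = NULL) {
  delim <- infer_delim(path, delim)
  df <- read.delim(path, sep = delim, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("host", "parasitoid", "weight")
  if (!all(need %in% names(df))) {
    stop_malformed(sprintf("edge list must have columns %s",
                           paste(need, collapse = ", ")))
  }
  if (!is.numeric(df$weight)) stop_malformed("edge weights must be numeric")
  if (!is.null(roster) && length(roster) == 1 && file.exists(roster)) {
    roster <- readLines(roster)
    roster <- roster[nzchar(trimws(roster))]
  }
  hosts <- unique(c(as.character(roster), as.character(df$host)))
  pars <- unique(as.character(df$parasitoid))
  a <- matrix(0, length(hosts), length(pars), dimnames = list(hosts, pars))
  for (k in seq_len(nrow(df))) {
    a[as.character(df$host[k]), as.character(df$parasitoid[k])] <-
      a[as.character(df$host[k]), as.character(df$parasitoid[k])] + df$weight[k]
  }
  quantweb_network(a, network_id = network_id, study_id = study_id,
                   latitude = latitude, guild = guild)
}

#' Write a network matrix to a delimited file
#'
#' Inverse of [read_network_matrix()]; round-trips integer networks
#' exactly.
#'
#' @inheritParams matrix_size
#' @inheritParams read_network_matrix
#' @return `path`, invisibly.
#' @export
write_network_matrix <- function(net, path, delim = NULL) {
  delim <- infer_delim(path, delim)
  df <- data.frame(host = rownames(net$a), net$a, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-network metadata
#'
#' @param path CSV/TSV with header `study_id,network_id,latitude,guild`.
#' @param delim Field delimiter; inferred from the extension when `NULL`.
#' @return A tibble with one row per network.
#' @export
read_metadata <- function(path, delim = NULL) {
  delim <- infer_delim(path, delim)
  df <- read.delim(path, sep = delim, stringsAsFactors = FALSE)
  need <- c("study_id", "network_id", "latitude", "guild")
  if (!all(need %in% names(df))) {
    stop_malformed(sprintf("metadata must have columns %s",
                           paste(need, collapse = ", ")))
  }
  as_tibble(df[need])
}

#' Bundle networks into a study collection
#'
#' A collection is the tabular unit the cross-network analyses operate
#' on: one row per network with its study membership, metadata and the
#' network object itself in a list-column.
#'
#' @param networks A list of [quantweb_network] objects.
#' @return A tibble of class `quantweb_collection` with columns
#'   `study_id`, `network_id`, `latitude`, `guild`, `m`, `n_hosts`,
#'   `n_parasitoids`, `is_integer` and list-column `network`.
#' @export
quantweb_collection <- function(networks) {
  if (inherits(networks, "quantweb_network")) networks <- list(networks)
  stopifnot(length(networks) >= 1,
            all(vapply(networks, inherits, TRUE, "quantweb_network")))
  out <- tibble(
    study_id = vapply(networks, `[[`, "", "study_id"),
    network_id = vapply(networks, `[[`, "", "network_id"),
    latitude = vapply(networks, `[[`, 0, "latitude"),
    guild = vapply(networks, `[[`, "", "guild"),
    m = vapply(networks, matrix_size, 0),
    n_hosts = vapply(networks, n_hosts, 0L),
    n_parasitoids = vapply(networks, n_parasitoids, 0L),
    is_integer = vapply(networks, `[[`, TRUE, "is_integer"),
    network = networks)
  if (anyDuplicated(out$network_id)) {
    stop_validation("network_id values must be unique within a collection")
  }
  class(out) <- c("quantweb_collection", class(out))
  out
}

#' @export
print.quantweb_collection <- function(x, ...) {
  cat(sprintf("<quantweb_collection> %d networks from %d studies\n",
              nrow(x), length(unique(x$study_id))))
  NextMethod()
}
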