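DIRECTION_LEVELS <- c("Up", "Down", "Even")
PATTERN_LEVELS <- c("stochastic_hypomethylation", "stochastic_hypermethylation",
                    "random_differential_methylation", "unclassified")

# The sixteen listed direction triples (generations 1, 3, 5): three
# monotone-decreasing patterns, three monotone-increasing, and ten
# non-monotone "random" ones; the remaining 11 of the 27 possible triples
# are left unclassified.
PATTERN_TABLE <- c(
  DDD = "stochastic_hypomethylation",
  EDD = "stochastic_hypomethylation",
  EED = "stochastic_hypomethylation",
  UUU = "stochastic_hypermethylation",
  EUU = "stochastic_hypermethylation",
  EEU = "stochastic_hypermethylation",
  DUD = "random_differential_methylation",
  DUE = "random_differential_methylation",
  DED = "random_differential_methylation",
  EUD = "random_differential_methylation",
  EUE = "random_differential_methylation",
  EDE = "random_differential_methylation",
  EDU = "random_differential_methylation",
  UDU = "random_differential_methylation",
  UDE = "random_differential_methylation",
  UEU = "random_differential_methylation")

#' Direction call for one generation comparison
#'
#' A probe is called \code{Up} (hypermethylated relative to the parental
#' channel) when its posterior probability of differential methylation is
#' at least \code{threshold} and its mean log signal difference (treated
#' minus control) is positive, \code{Down} when the difference is
#' negative, and \code{Even} otherwise (including any probe below the
#' posterior threshold, or with zero difference).
#'
#' @param Z posterior probability vector (values in [0, 1]).
#' @param delta mean log signal difference, treated minus control.
#' @param threshold posterior calling threshold (default 0.8).
#' @return character vector of \code{"Up"}, \code{"Down"}, \code{"Even"}.
#' @export
direction_call <- function(Z, delta, threshold = 0.8) {
  stopifnot(length(Z) == length(delta), all(Z >= 0 & Z <= 1),
            all(is.finite(delta)))
  out <- rep("Even", length(Z))
  out[Z >= threshold & delta > 0] <- "Up"
  out[Z >= threshold & delta < 0] <- "Down"
  out
}

#' Heritability category for a generation triple of direction calls
#'
#' Maps a triple of per-generation direction calls (generations 1, 3, 5
#' versus parental) to one of the time-dependent methylation pattern
#' categories: progressive loss (\emph{stochastic hypomethylation}:
#' Down-Down-Down, Even-Down-Down, Even-Even-Down), progressive gain
#' (\emph{stochastic hypermethylation}: the Up mirror images), one of the
#' ten listed non-monotone triples (\emph{random differential
#' methylation}), or \emph{unclassified} for the remaining 11 triples.
#'
#' @param calls character vector of exactly three direction calls
#'   (\code{"Up"}/\code{"Down"}/\code{"Even"}), in generation order, or a
#'   matrix with three columns (one row per probe).
#' @return category string (or vector, for matrix input).
#' @export
classify_pattern <- function(calls) {
  if (is.matrix(calls) || is.data.frame(calls)) {
    calls <- as.matrix(calls)
    if (ncol(calls) != 3) stop("classify_pattern: need exactly 3 calls per probe")
    return(apply(calls, 1, classify_pattern))
  }
  if (length(calls) != 3) stop("classify_pattern: need exactly 3 calls")
  if (!all(calls %in% DIRECTION_LEVELS))
    stop("classify_pattern: calls must be Up/Down/Even")
  key <- paste(substr(calls, 1, 1), collapse = "")
  key <- chartr("UDE", "UDE", key)
  got <- PATTERN_TABLE[key]
  if (is.na(got)) "unclassified" else unname(got)
}

#' Tabulate heritability categories over probes
#'
#' @param calls matrix or data frame with three columns of direction calls
#'   (generations 1, 3, 5), one row per probe; rownames (or a
#'   \code{probe_id} column) identify probes.
#' @return list with \code{counts} (named integer vector over the four
#'   categories), \code{category} (per-probe assignment) and
#'   \code{probes_by_category}.
#' @export
tabulate_patterns <- function(calls) {
  calls_df <- as.data.frame(calls, stringsAsFactors = FALSE)
  ids <- if ("probe_id" %in% names(calls_df)) {
    out <- calls_df$probe_id
    calls_df$probe_id <- NULL
    out
  } else if (!is.null(rownames(calls))) rownames(calls) else
    as.character(seq_len(nrow(calls_df)))
  m <- as.matrix(calls_df)
  if (nrow(m) == 0) {
    counts <- stats::setNames(integer(length(PATTERN_LEVELS)), PATTERN_LEVELS)
    return(list(counts = counts, category = character(0),
                probes_by_category = stats::setNames(
                  vector("list", length(PATTERN_LEVELS)), PATTERN_LEVELS)))
  }
  bad <- matrix(is.na(m) | !(m %in% DIRECTION_LEVELS), nrow(m))
  incomplete <- rowSums(bad) > 0
  skipped <- ids[incomplete]
  if (length(skipped) > 0) {
    warning("skipping probe(s) with missing/invalid calls: ",
            paste(utils::head(skipped, 10), collapse = ", "))
    m <- m[!incomplete, , drop = FALSE]
    ids <- ids[!incomplete]
  }
  cat_vec <- if (nrow(m) > 0) classify_pattern(m) else character(0)
  counts <- stats::setNames(
    vapply(PATTERN_LEVELS, function(p) sum(cat_vec == p), integer(1)),
    PATTERN_LEVELS)
  list(counts = counts,
       category = stats::setNames(cat_vec, ids),
       probes_by_category = stats::setNames(
         lapply(PATTERN_LEVELS, function(p) ids[cat_vec == p]),
         PATTERN_LEVELS),
       skipped = skipped)
}

#' Three-way posterior classification of probes
#'
#' Labels each probe by its posterior probability of differential
#' methylation: \code{"differential"} when \eqn{Z_i \ge} \code{upper}
#' (default 0.8), \code{"non_differential"} when \eqn{Z_i \le}
#' \code{lower} (default 0.2), \code{"undetermined"} otherwise.
#'
#' @param Z posterior probability vector.
#' @param upper,lower classification thresholds.
#' @return character vector of labels.
#' @export
classify_posterior <- function(Z, upper = 0.8, lower = 0.2) {
  stopifnot(all(Z >= 0 & Z <= 1), lower <= upper)
  out <- rep("undetermined", length(Z))
  out[Z >= upper] <- "differential"
  out[Z <= lower] <- "non_differential"
  out
}
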