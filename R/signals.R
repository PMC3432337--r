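CHANNELS <- c("treated", "control")

#' Compute probe methylation signals and standard errors
#'
#' Converts raw two-color probe records (foreground/background intensity,
#' per-spot pixel SD and pixel counts) into the per-probe methylation signal
#' \eqn{y = |F - B|}, its standard error
#' \eqn{\sigma = \sqrt{SD_F^2/Pix_F + SD_B^2/Pix_B}}, the relative standard
#' error \eqn{\sigma' = \sigma / y} and the log signal \eqn{y' = \log y}.
#'
#' Probes whose foreground equals background (\eqn{y = 0}) cannot be placed
#' on the log scale; they are flagged \code{valid = FALSE} and their
#' \code{sigma_rel} and \code{y_log} are \code{NA}.
#'
#' @param records data frame of raw probe records with columns
#'   \code{probe_id}, \code{channel} (\code{"treated"} for Cy5,
#'   \code{"control"} for Cy3), \code{replicate}, \code{F}, \code{B},
#'   \code{SD_F}, \code{SD_B}, \code{Pix_F}, \code{Pix_B}, as returned by
#'   \code{\link{read_probe_table}}.
#' @param log_base base of the log transform; \code{exp(1)} (natural log,
#'   the default) or any base > 1 such as 2.
#' @return data frame with columns \code{probe_id}, \code{channel},
#'   \code{replicate}, \code{y}, \code{sigma}, \code{sigma_rel},
#'   \code{y_log}, \code{valid}.
#' @examples
#' rec <- data.frame(probe_id = "p1", channel = "treated", replicate = 1L,
#'                   F = 1000, B = 100, SD_F = 50, SD_B = 10,
#'                   Pix_F = 25, Pix_B = 25)
#' compute_signal(rec)
#' @export
compute_signal <- function(records, log_base = exp(1)) {
  records <- validate_raw_records(records)
  y <- abs(records$F - records$B)
  sigma <- sqrt(records$SD_F^2 / records$Pix_F + records$SD_B^2 / records$Pix_B)
  valid <- y > 0
  sigma_rel <- ifelse(valid, sigma / y, NA_real_)
  y_log <- ifelse(valid, log(y) / log(log_base), NA_real_)
  data.frame(
    probe_id = records$probe_id,
    channel = records$channel,
    replicate = records$replicate,
    y = y, sigma = sigma, sigma_rel = sigma_rel, y_log = y_log,
    valid = valid,
    stringsAsFactors = FALSE
  )
}

validate_raw_records <- function(records) {
  req <- c("probe_id", "channel", "replicate", "F", "B",
           "SD_F", "SD_B", "Pix_F", "Pix_B")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0) return(records)
  bad_chan <- !records$channel %in% CHANNELS
  if (any(bad_chan)) {
    stop("unknown channel value(s): ",
         paste(unique(records$channel[bad_chan]), collapse = ", "),
         " (expected 'treated' or 'control')")
  }
  bad_pix <- records$Pix_F < 1 | records$Pix_B < 1
  if (any(bad_pix)) {
    stop("malformed record: pixel count < 1 for probe(s) ",
         paste(unique(records$probe_id[bad_pix]), collapse = ", "))
  }
  bad_sd <- records$SD_F < 0 | records$SD_B < 0
  if (any(bad_sd)) {
    stop("malformed record: negative pixel SD for probe(s) ",
         paste(unique(records$probe_id[bad_sd]), collapse = ", "))
  }
  records
}

#' Read a probe-level two-color array table
#'
#' Reads either the canonical tab-separated dialect (one row per probe,
#' channel and replicate) or a GenePix-results-like table (one row per spot
#' carrying both wavelengths; Cy5 = 635 nm = treated, Cy3 = 532 nm =
#' control).
#'
#' @param path path to a tab-separated text file with a header row.
#' @param dialect \code{"tsv"} for the canonical dialect with columns
#'   \code{probe_id channel replicate F B SD_F SD_B Pix_F Pix_B}, or
#'   \code{"gpr_like"} for a GenePix-style table.
#' @param column_map optional named character vector remapping canonical
#'   column names to the file's column names, e.g.
#'   \code{c(probe_id = "ID")}.
#' @param replicate replicate index assigned to all rows of a
#'   \code{gpr_like} file (one scan per file).
#' @param swap_channels set \code{TRUE} if Cy5 carried the control sample.
#' @return data frame of raw probe records (one row per probe, channel and
#'   replicate), in file order.
#' @export
read_probe_table <- function(path, dialect = c("tsv", "gpr_like"),
                             column_map = NULL, replicate = 1L,
                             swap_channels = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (dialect == "tsv") {
    records <- parse_canonical_table(tab, column_map, path)
  } else {
    records <- parse_gpr_table(tab, column_map, path, replicate)
  }
  if (swap_channels && nrow(records) > 0) {
    records$channel <- ifelse(records$channel == "treated",
                              "control", "treated")
  }
  validate_raw_records(records)
}

resolve_columns <- function(tab, canonical, column_map, path) {
  actual <- canonical
  if (!is.null(column_map)) {
    hit <- names(column_map)[names(column_map) %in% canonical]
    actual[match(hit, canonical)] <- unname(column_map[hit])
  }
  missing_cols <- canonical[!actual %in% names(tab)]
  if (length(missing_cols) > 0) {
    stop("schema error in ", path, ": missing required column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  stats::setNames(actual, canonical)
}

parse_numeric_col <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad) > 0) {
    stop("parse error in ", path, ", column '", col, "', data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": non-numeric value")
  }
  out
}

parse_canonical_table <- function(tab, column_map, path) {
  canonical <- c("probe_id", "channel", "replicate", "F", "B",
                 "SD_F", "SD_B", "Pix_F", "Pix_B")
  cols <- resolve_columns(tab, canonical, column_map, path)
  num_cols <- c("replicate", "F", "B", "SD_F", "SD_B", "Pix_F", "Pix_B")
  out <- data.frame(
    probe_id = as.character(tab[[cols["probe_id"]]]),
    channel = as.character(tab[[cols["channel"]]]),
    stringsAsFactors = FALSE
  )
  for (cc in num_cols) out[[cc]] <- parse_numeric_col(tab[[cols[cc]]], cols[cc], path)
  out$replicate <- as.integer(out$replicate)
  out[, canonical]
}

parse_gpr_table <- function(tab, column_map, path, replicate) {
  canonical <- c("ID", "F635 Median", "B635 Median", "F635 SD", "B635 SD",
                 "F635 Pixels", "B635 Pixels",
                 "F532 Median", "B532 Median", "F532 SD", "B532 SD",
                 "F532 Pixels", "B532 Pixels")
  cols <- resolve_columns(tab, canonical, column_map, path)
  get_num <- function(cc) parse_numeric_col(tab[[cols[cc]]], cols[cc], path)
  ids <- as.character(tab[[cols["ID"]]])
  one_channel <- function(prefix, channel) {
    data.frame(
      probe_id = ids, channel = channel,
      replicate = as.integer(replicate),
      F = get_num(paste0("F", prefix, " Median")),
      B = get_num(paste0("B", prefix, " Median")),
      SD_F = get_num(paste0("F", prefix, " SD")),
      SD_B = get_num(paste0("B", prefix, " SD")),
      Pix_F = get_num(paste0("F", prefix, " Pixels")),
      Pix_B = get_num(paste0("B", prefix, " Pixels")),
      stringsAsFactors = FALSE
    )
  }
  rbind(one_channel("635", "treated"), one_channel("532", "control"))
}

#' Write raw probe records in the canonical TSV dialect
#'
#' @param records data frame of raw probe records.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_probe_table <- function(records, path) {
  canonical <- c("probe_id", "channel", "replicate", "F", "B",
                 "SD_F", "SD_B", "Pix_F", "Pix_B")
  utils::write.table(records[, canonical], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write computed signals in the canonical signal TSV
#'
#' @param signals data frame from \code{\link{compute_signal}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_signal_table <- function(signals, path) {
  cols <- c("probe_id", "channel", "replicate", "y", "sigma",
            "sigma_rel", "y_log", "valid")
  extra <- intersect("correction", names(signals))
  utils::write.table(signals[, c(cols, extra)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a methylation dataset from raw probe records
#'
#' Computes signals via \code{\link{compute_signal}} and arranges them as
#' probes-by-replicates matrices per channel, together with the matching
#' known standard errors (\eqn{\sigma} on the linear scale, the relative SE
#' \eqn{\sigma'} on the log scale). On the log scale, probes with any
#' zero-signal replicate are excluded (a log signal cannot be formed) and
#' the number excluded is recorded in the result.
#'
#' @param records data frame of raw probe records
#'   (\code{\link{read_probe_table}}).
#' @param scale \code{"linear"} (gamma-family models) or \code{"log"}
#'   (log-normal models).
#' @param generation_label free-text label for the comparison, e.g.
#'   \code{"gen1"}.
#' @param log_base log base for the log scale (natural log by default).
#' @return an object of class \code{meth_dataset}: a list with
#'   \code{probe_ids}, matrices \code{treated}/\code{control} (signals),
#'   \code{se_treated}/\code{se_control} (known SEs), \code{scale},
#'   \code{generation_label} and \code{n_excluded}.
#' @export
build_dataset <- function(records, scale = c("linear", "log"),
                          generation_label = "", log_base = exp(1)) {
  scale <- match.arg(scale)
  sig <- compute_signal(records, log_base = log_base)
  key <- paste(sig$probe_id, sig$channel, sig$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- sig$probe_id[duplicated(key)]
    stop("duplicate (probe, channel, replicate) record(s) for probe(s): ",
         paste(unique(dup), collapse = ", "))
  }
  ids <- unique(sig$probe_id)
  has_t <- ids %in% sig$probe_id[sig$channel == "treated"]
  has_c <- ids %in% sig$probe_id[sig$channel == "control"]
  lonely <- ids[!(has_t & has_c)]
  if (length(lonely) > 0) {
    stop("probe(s) present in only one channel: ",
         paste(lonely, collapse = ", "))
  }

  n_excluded <- 0L
  if (scale == "log") {
    bad_ids <- unique(sig$probe_id[!sig$valid])
    n_excluded <- length(bad_ids)
    ids <- setdiff(ids, bad_ids)
    sig <- sig[sig$probe_id %in% ids, , drop = FALSE]
    if (length(ids) == 0) stop("no probes remain after excluding zero-signal probes")
  }

  ch_matrix <- function(channel, value_col) {
    sub <- sig[sig$channel == channel, , drop = FALSE]
    reps <- sort(unique(sub$replicate))
    counts <- table(factor(sub$probe_id, levels = ids))
    if (any(counts != length(reps))) {
      stop("ragged replicate structure in channel '", channel,
           "': every probe must carry the same replicate set")
    }
    m <- matrix(NA_real_, length(ids), length(reps),
                dimnames = list(ids, paste0("rep", reps)))
    m[cbind(match(sub$probe_id, ids), match(sub$replicate, reps))] <-
      sub[[value_col]]
    m
  }
  val_col <- if (scale == "log") "y_log" else "y"
  se_col <- if (scale == "log") "sigma_rel" else "sigma"
  structure(list(
    probe_ids = ids,
    treated = ch_matrix("treated", val_col),
    control = ch_matrix("control", val_col),
    se_treated = ch_matrix("treated", se_col),
    se_control = ch_matrix("control", se_col),
    scale = scale,
    generation_label = generation_label,
    log_base = log_base,
    n_excluded = n_excluded
  ), class = "meth_dataset")
}

#' Construct a methylation dataset from matrices
#'
#' Low-level constructor used by the simulators and by callers that already
#' hold probes-by-replicates signal matrices.
#'
#' @param treated,control numeric matrices (probes x replicates) of signals.
#' @param se_treated,se_control matching known-SE matrices, or \code{NULL}.
#' @param scale \code{"linear"} or \code{"log"}.
#' @param probe_ids character vector of probe ids (defaults to
#'   \code{probe_1 ... probe_n}).
#' @param generation_label free-text label.
#' @return a \code{meth_dataset}.
#' @export
meth_dataset <- function(treated, control, se_treated = NULL,
                         se_control = NULL, scale = c("linear", "log"),
                         probe_ids = NULL, generation_label = "") {
  scale <- match.arg(scale)
  treated <- as.matrix(treated); control <- as.matrix(control)
  if (nrow(treated) != nrow(control))
    stop("treated and control must have the same number of probes")
  if (is.null(probe_ids))
    probe_ids <- paste0("probe_", seq_len(nrow(treated)))
  if (scale == "linear" && (any(treated < 0) || any(control < 0)))
    stop("negative linear signals are not allowed")
  chk_se <- function(se, sig, nm) {
    if (is.null(se)) return(NULL)
    se <- as.matrix(se)
    if (!all(dim(se) == dim(sig)))
      stop(nm, " must match the signal matrix dimensions")
    if (any(se < 0)) stop(nm, " must be nonnegative")
    se
  }
  structure(list(
    probe_ids = probe_ids,
    treated = treated, control = control,
    se_treated = chk_se(se_treated, treated, "se_treated"),
    se_control = chk_se(se_control, control, "se_control"),
    scale = scale,
    generation_label = generation_label,
    log_base = exp(1),
    n_excluded = 0L
  ), class = "meth_dataset")
}

#' @export
print.meth_dataset <- function(x, ...) {
  cat(sprintf(
    "meth_dataset: %d probes, %d+%d replicates (treated+control), %s scale%s\n",
    length(x$probe_ids), ncol(x$treated), ncol(x$control), x$scale,
    if (nzchar(x$generation_label)) paste0(", ", x$generation_label) else ""))
  if (x$n_excluded > 0)
    cat(sprintf("  %d probe(s) excluded (zero signal on log scale)\n",
                x$n_excluded))
  invisible(x)
}

n_probes <- function(dataset) length(dataset$probe_ids)

#' Subset a methylation dataset by probe
#'
#' @param dataset a \code{meth_dataset}.
#' @param idx integer, logical or character (probe id) index.
#' @return the subsetted \code{meth_dataset}.
#' @export
subset_dataset <- function(dataset, idx) {
  if (is.character(idx)) idx <- match(idx, dataset$probe_ids)
  dataset$probe_ids <- dataset$probe_ids[idx]
  for (f in c("treated", "control", "se_treated", "se_control")) {
    if (!is.null(dataset[[f]])) dataset[[f]] <- dataset[[f]][idx, , drop = FALSE]
  }
  dataset
}
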