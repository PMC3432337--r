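#' Generate GC- and length-matched background sequences
#'
#' Builds \code{n} random background sequences matched to a category of
#' promoter sequences: the i-th background sequence copies the length of a
#' category sequence (cycling through the category in order) and draws its
#' bases i.i.d. at that sequence's GC fraction (G and C equiprobable, A
#' and T equiprobable). Deterministic given \code{seed}.
#'
#' @param category_sequences named character vector or
#'   \code{Biostrings::DNAStringSet} of sequences over A/C/G/T.
#' @param n number of background sequences (default 10000).
#' @param seed integer seed.
#' @return named character vector of \code{n} background sequences
#'   (\code{bg_1 ... bg_n}).
#' @export
generate_background <- function(category_sequences, n = 10000, seed = 1) {
  seqs <- as_sequence_vector(category_sequences)
  if (length(seqs) == 0) stop("generate_background: empty category")
  check_acgt(seqs)
  if (n == 0) return(stats::setNames(character(0), character(0)))
  lens <- nchar(seqs)
  gc <- vapply(strsplit(seqs, ""), function(b) mean(b %in% c("G", "C")),
               numeric(1))
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    out <- character(n)
    for (i in seq_len(n)) {
      j <- ((i - 1) %% length(seqs)) + 1
      pgc <- unname(gc[j])
      probs <- c((1 - pgc) / 2, pgc / 2, pgc / 2, (1 - pgc) / 2)
      out[i] <- paste(sample(bases, lens[j], replace = TRUE, prob = probs),
                      collapse = "")
    }
    stats::setNames(out, paste0("bg_", seq_len(n)))
  })
}

as_sequence_vector <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    v <- as.character(x)
    if (is.null(names(v))) names(v) <- paste0("seq_", seq_along(v))
    return(v)
  }
  v <- stats::setNames(as.character(x), names(x))
  if (is.null(names(v)) && length(v) > 0)
    names(v) <- paste0("seq_", seq_along(v))
  v
}

check_acgt <- function(seqs) {
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGT]", seqs[i])
    if (bad > 0) {
      stop("non-ACGT character in sequence '", names(seqs)[i],
           "' at position ", bad)
    }
  }
  invisible(TRUE)
}

#' Read FASTA sequences as a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  v <- toupper(as.character(ss))
  names(v) <- sub("\\s.*$", "", names(v))
  v
}

#' Parse TRANSFAC-style position weight matrices
#'
#' Reads plain-text matrix blocks: an accession line (\code{AC} or
#' \code{ID}) naming the matrix, a \code{P0 A C G T} header, numbered
#' position rows of four counts, and \code{//} terminating each block.
#'
#' @param path path to the matrix file.
#' @return named list of L x 4 numeric matrices (columns A, C, G, T).
#' @export
read_transfac_matrices <- function(path) {
  lines <- readLines(path)
  mats <- list()
  acc <- NULL
  rows <- NULL
  flush <- function() {
    if (!is.null(acc)) {
      if (is.null(rows) || nrow(rows) == 0)
        stop("malformed matrix block for accession ", acc, ": no position rows")
      mats[[acc]] <<- rows
    }
    acc <<- NULL; rows <<- NULL
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" ) next
    if (startsWith(ln, "//")) { flush(); next }
    tag <- sub("^([A-Z0-9]+)\\s.*$", "\\1", ln)
    if (tag %in% c("AC", "ID", "NA")) {
      val <- trimws(sub("^[A-Z]+\\s+", "", ln))
      if (tag == "AC" || is.null(acc)) acc <- val
      next
    }
    if (grepl("^P0", ln) || grepl("^PO", ln)) { rows <- NULL; next }
    if (grepl("^[0-9]+\\s", ln)) {
      parts <- strsplit(ln, "\\s+")[[1]]
      if (length(parts) < 5)
        stop("malformed matrix block for accession ",
             if (is.null(acc)) "<unknown>" else acc,
             ": position row with fewer than 4 counts")
      vals <- suppressWarnings(as.numeric(parts[2:5]))
      if (any(is.na(vals)))
        stop("malformed matrix block for accession ",
             if (is.null(acc)) "<unknown>" else acc,
             ": non-numeric count")
      row <- matrix(vals, 1, dimnames = list(NULL, c("A", "C", "G", "T")))
      rows <- rbind(rows, row)
    }
  }
  flush()
  mats
}

# Matrix-similarity machinery: positions are weighted by their information
# content I(p) = sum_b f_pb log(4 f_pb); a window scores
# S = sum_p I(p) f_{p, b_p}, normalized to [0, 1] by the per-matrix
# minimum and maximum achievable S.
pwm_profile <- function(mat) {
  freq <- mat / pmax(rowSums(mat), 1e-300)
  info <- rowSums(ifelse(freq > 0, freq * log(4 * freq), 0))
  w <- freq * info
  list(w = w, smin = sum(apply(w, 1, min)), smax = sum(apply(w, 1, max)))
}

revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

scan_one <- function(seq_chars, prof, threshold) {
  L <- length(seq_chars)
  w <- prof$w
  width <- nrow(w)
  if (L < width) return(0L)
  idx <- match(seq_chars, c("A", "C", "G", "T"))
  n_win <- L - width + 1
  scores <- numeric(n_win)
  for (p in seq_len(width)) {
    scores <- scores + w[p, ][idx[p:(p + n_win - 1)]]
  }
  denom <- prof$smax - prof$smin
  mss <- if (denom > 0) (scores - prof$smin) / denom else rep(1, n_win)
  sum(mss >= threshold)
}

#' Scan sequences with position weight matrices
#'
#' Scores every window of every sequence on both strands with the
#' information-weighted matrix-similarity score
#' \eqn{(S - S_{min}) / (S_{max} - S_{min})} and counts windows scoring at
#' least \code{score_threshold} as hits.
#'
#' @param sequences named character vector (or \code{DNAStringSet}) of
#'   A/C/G/T sequences.
#' @param matrices named list of L x 4 count matrices
#'   (\code{\link{read_transfac_matrices}}).
#' @param score_threshold matrix-similarity threshold in [0, 1]
#'   (default 0.85).
#' @return a \code{hit_table}: list with \code{counts} (sequences x
#'   matrices integer matrix of hit counts), \code{tf_ids},
#'   \code{sequence_ids}.
#' @export
scan_pwm <- function(sequences, matrices, score_threshold = 0.85) {
  seqs <- as_sequence_vector(sequences)
  check_acgt(seqs)
  if (score_threshold < 0 || score_threshold > 1)
    stop("score_threshold must be in [0, 1]")
  for (nm in names(matrices)) {
    m <- matrices[[nm]]
    if (!is.matrix(m) || ncol(m) != 4 || nrow(m) < 1)
      stop("matrix '", nm, "' must have >= 1 position and 4 columns")
  }
  profs <- lapply(matrices, pwm_profile)
  rc <- if (length(seqs) > 0) revcomp(seqs) else character(0)
  counts <- matrix(0L, length(seqs), length(matrices),
                   dimnames = list(names(seqs), names(matrices)))
  split_fwd <- strsplit(seqs, "")
  split_rev <- strsplit(rc, "")
  for (j in seq_along(profs)) {
    for (i in seq_along(seqs)) {
      counts[i, j] <- scan_one(split_fwd[[i]], profs[[j]], score_threshold) +
        scan_one(split_rev[[i]], profs[[j]], score_threshold)
    }
  }
  structure(list(counts = counts, tf_ids = names(matrices),
                 sequence_ids = names(seqs)),
            class = "hit_table")
}

#' One-sided Fisher enrichment p-value
#'
#' P-value of Fisher's exact test, alternative "greater", on the 2x2 table
#' of sequences with versus without a hit in the category against the
#' background.
#'
#' @param k_cat category sequences with >= 1 hit.
#' @param n_cat category size.
#' @param k_bg background sequences with >= 1 hit.
#' @param n_bg background size.
#' @return p-value in [0, 1].
#' @export
fisher_enrichment <- function(k_cat, n_cat, k_bg, n_bg) {
  stopifnot(k_cat >= 0, k_bg >= 0, k_cat <= n_cat, k_bg <= n_bg)
  tab <- matrix(c(k_cat, n_cat - k_cat, k_bg, n_bg - k_bg), 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Bonferroni family-wise threshold for TFBS enrichment
#'
#' @param alpha family-wise error level, in (0, 1).
#' @param n_tf number of transcription factor matrices tested
#'   (default 459).
#' @param n_categories number of sequence categories tested (default 3).
#' @return per-test p-value threshold \code{alpha / (n_tf * n_categories)}.
#' @examples
#' bonferroni_threshold(0.05, 459, 3)   # 3.63e-05
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tf = 459, n_categories = 3) {
  stopifnot(alpha > 0, alpha < 1, n_tf >= 1, n_categories >= 1)
  alpha / (n_tf * n_categories)
}

#' Enrichment of TFBS hits per category against background
#'
#' For each (category, matrix) pair, counts sequences carrying at least
#' one hit, tests enrichment against the background hit table by
#' \code{\link{fisher_enrichment}}, and flags significance under the
#' Bonferroni threshold.
#'
#' @param category_hits named list of \code{hit_table}s, one per category.
#' @param background_hits \code{hit_table} for the background set.
#' @param alpha family-wise error level.
#' @param n_tf_override if not \code{NULL}, the matrix count used for the
#'   Bonferroni divisor (e.g. 459) instead of the tf universe size.
#' @return data frame with columns \code{category tf_id k_cat n_cat k_bg
#'   n_bg sites_cat p_value significant}.
#' @export
enrich_categories <- function(category_hits, background_hits, alpha = 0.05,
                              n_tf_override = NULL) {
  stopifnot(inherits(background_hits, "hit_table"), length(category_hits) >= 1)
  tf <- background_hits$tf_ids
  for (nm in names(category_hits)) {
    h <- category_hits[[nm]]
    stopifnot(inherits(h, "hit_table"))
    if (!setequal(h$tf_ids, tf)) {
      stop("tf universe mismatch for category '", nm, "': ",
           paste(union(setdiff(h$tf_ids, tf), setdiff(tf, h$tf_ids)),
                 collapse = ", "))
    }
  }
  if (is.null(names(category_hits)))
    names(category_hits) <- paste0("category_", seq_along(category_hits))
  n_bg <- length(background_hits$sequence_ids)
  if (n_bg == 0) stop("empty background")
  n_tf_eff <- if (is.null(n_tf_override)) length(tf) else n_tf_override
  thr <- bonferroni_threshold(alpha, n_tf_eff, length(category_hits))
  k_bg <- colSums(background_hits$counts[, tf, drop = FALSE] > 0)
  out <- do.call(rbind, lapply(names(category_hits), function(nm) {
    h <- category_hits[[nm]]
    n_cat <- length(h$sequence_ids)
    k_cat <- colSums(h$counts[, tf, drop = FALSE] > 0)
    sites <- colSums(h$counts[, tf, drop = FALSE])
    pv <- vapply(seq_along(tf), function(j)
      fisher_enrichment(k_cat[j], n_cat, k_bg[j], n_bg), numeric(1))
    data.frame(category = nm, tf_id = tf, k_cat = as.integer(k_cat),
               n_cat = n_cat, k_bg = as.integer(k_bg), n_bg = n_bg,
               sites_cat = as.integer(sites), p_value = pv,
               significant = pv < thr,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  attr(out, "bonferroni_threshold") <- thr
  out
}
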