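# Probabilistic template selection: BLOSUM62 sequence scoring combined with
# template resolution, normalized over the length-matched sub-library.

blosum_env <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' Lazily loads the standard BLOSUM62 matrix shipped with Biostrings.
#'
#' @return Integer matrix with one-letter amino-acid row/column names.
#' @export
blosum62 <- function() {
  if (is.null(blosum_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum_env$m <- e$BLOSUM62
  }
  blosum_env$m
}

check_seq <- function(x, what) {
  if (!is.character(x) || length(x) != 1)
    cyc_error("cycpep_domain_error", paste0(what, " must be a single string"))
  letters1 <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(letters1, AA1)
  if (length(bad) > 0)
    cyc_error("cycpep_domain_error",
              paste0("unknown amino-acid letter(s) in ", what, ": ",
                     paste(unique(bad), collapse = ", ")))
  letters1
}

#' Position-wise BLOSUM62 score between two equal-length sequences
#'
#' Gapless sum of BLOSUM62 entries over aligned positions; this is the
#' sequence-similarity term s_i of the template-selection probability.
#'
#' @param target_seq,template_seq one-letter strings of equal length.
#' @return Integer score (can be negative).
#' @export
sequence_score <- function(target_seq, template_seq) {
  a <- check_seq(target_seq, "target_seq")
  b <- check_seq(template_seq, "template_seq")
  if (length(a) != length(b))
    cyc_error("cycpep_domain_error", "sequences must have equal length")
  m <- blosum62()
  sum(m[cbind(a, b)])
}

#' Percent identity between two equal-length sequences
#'
#' Exact-match fraction over the cyclic span, in percent.
#'
#' @inheritParams sequence_score
#' @return Percentage in \[0, 100\].
#' @export
percent_identity <- function(target_seq, template_seq) {
  a <- check_seq(target_seq, "target_seq")
  b <- check_seq(template_seq, "template_seq")
  if (length(a) != length(b))
    cyc_error("cycpep_domain_error", "sequences must have equal length")
  100 * mean(a == b)
}

#' Template-selection weights
#'
#' Weight of the sequence-similarity term (`w_s`, default 6.0) and of the
#' resolution term (`w_r`, default -1.0) in the selection probability, plus
#' the resolution substituted for templates whose source structure reports
#' none (default 3.0 Angstrom).
#'
#' @param w_s,w_r finite numeric weights.
#' @param default_resolution Angstrom.
#' @return A `selection_weights` list.
#' @export
selection_weights <- function(w_s = 6.0, w_r = -1.0, default_resolution = 3.0) {
  stopifnot(is.finite(w_s), is.finite(w_r), is.finite(default_resolution),
            default_resolution > 0)
  structure(list(w_s = w_s, w_r = w_r, default_resolution = default_resolution),
            class = "selection_weights")
}

#' Selection probabilities over a sub-library
#'
#' For each representative i the raw weight is
#' `exp(w_s * s_i / s_max + w_r * r_i / r_max)`, where s_i is the BLOSUM62
#' score against the target cyclic sequence and r_i the template resolution
#' (defaulted when absent); probabilities are the raw weights normalized to
#' sum to 1 over the sub-library.  When `s_max <= 0` (possible for short
#' fragments with all-negative scores) the sequence term is dropped rather
#' than divided by a non-positive maximum.
#'
#' @param templates list of `cyclic_fragment` representatives of one length
#'   (as returned by [sub_library()]).
#' @param target_cyclic_seq one-letter string with the target's cyclic span.
#' @param weights a [selection_weights()] object.
#' @return data.frame with columns `template_index`, `s`, `r`, `probability`,
#'   in sub-library order.
#' @export
template_probabilities <- function(templates, target_cyclic_seq,
                                   weights = selection_weights()) {
  if (length(templates) == 0)
    cyc_error("cycpep_no_template", "sub-library is empty")
  n_cyc <- templates[[1]]$length
  if (nchar(target_cyclic_seq) != n_cyc)
    cyc_error("cycpep_domain_error",
              "target cyclic sequence length does not match sub-library length")
  s <- vapply(templates, function(f) sequence_score(target_cyclic_seq, f$sequence),
              numeric(1))
  r <- vapply(templates, function(f)
    ifelse(is.na(f$resolution), weights$default_resolution, f$resolution),
    numeric(1))
  s_max <- max(s)
  r_max <- max(r)
  s_term <- if (s_max > 0) weights$w_s * s / s_max else rep(0, length(s))
  raw <- exp(s_term + weights$w_r * r / r_max)
  data.frame(template_index = seq_along(templates), s = s, r = r,
             probability = raw / sum(raw))
}

#' Draw a template index from selection probabilities
#'
#' Categorical draw using the current RNG state; reproducible under a fixed
#' seed.
#'
#' @param scores data.frame from [template_probabilities()].
#' @param n number of draws.
#' @return Integer vector of template indices.
#' @export
sample_template <- function(scores, n = 1) {
  stopifnot(is.data.frame(scores), "probability" %in% names(scores))
  p <- scores$probability
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must be normalized")
  scores$template_index[sample.int(length(p), n, replace = TRUE, prob = p)]
}

#' Remove templates too similar to the target sequence
#'
#' Drops representatives whose percent identity to the target is greater than
#' or equal to `identity_cutoff` (so a cutoff of 100 removes exact sequence
#' matches only).  Used for leave-similarity-out ablations.
#'
#' @param templates list of `cyclic_fragment` representatives of one length.
#' @param target_cyclic_seq one-letter target cyclic sequence.
#' @param identity_cutoff percentage in (0, 100].
#' @return Filtered list of templates.
#' @export
filter_by_identity <- function(templates, target_cyclic_seq, identity_cutoff) {
  stopifnot(identity_cutoff > 0, identity_cutoff <= 100)
  keep <- vapply(templates, function(f)
    percent_identity(target_cyclic_seq, f$sequence) < identity_cutoff,
    logical(1))
  out <- templates[keep]
  if (length(out) == 0)
    cyc_error("cycpep_no_template",
              "identity filtering removed every template in the sub-library")
  out
}
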