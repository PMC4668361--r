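#' Somatic-hypermutation repertoire configuration
#'
#' Parameters of the synthetic repertoire generator: the number of sequences,
#' an independent per-position substitution probability (optionally weighted by
#' position), the substitution model, and variants planted at controlled
#' frequencies so downstream mining has a known truth.
#'
#' @param n_sequences Number of sequences to simulate.
#' @param per_position_rate Probability that a given position of a given
#'   sequence carries a background somatic substitution.
#' @param position_weights Optional named numeric vector (names = Kabat
#'   numbers) of relative hotspot weights; the realized per-position rate is
#'   `per_position_rate * weight / mean(weight)`.
#' @param substitution_model `"uniform"` draws the replacement uniformly from
#'   the 19 alternatives; `"transition_biased"` favours chemically similar
#'   replacements (a simple similarity-weighted table).
#' @param planted_variants Data frame with columns `number`, `to_aa`,
#'   `target_frequency` (optional `insertion`); each sequence independently
#'   carries each planted variant with its target frequency.
#' @param seed Integer seed; the generator is reproducible for a fixed seed.
#' @return An `shm_config` list.
#' @export
shm_config <- function(n_sequences, per_position_rate = 0.01,
                       position_weights = NULL,
                       substitution_model = c("uniform", "transition_biased"),
                       planted_variants = NULL, seed = 1L) {
  stopifnot(
    n_sequences >= 1,
    per_position_rate >= 0, per_position_rate <= 1,
    is.null(position_weights) || all(position_weights >= 0)
  )
  if (!is.null(planted_variants)) {
    stopifnot(
      all(c("number", "to_aa", "target_frequency") %in% names(planted_variants)),
      all(planted_variants$target_frequency >= 0),
      all(planted_variants$target_frequency <= 1)
    )
    if (is.null(planted_variants$insertion)) planted_variants$insertion <- ""
    key <- kabat_label(planted_variants$number, planted_variants$insertion)
    if (anyDuplicated(key)) {
      stop("conflicting planted variants at position(s): ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    }
  }
  structure(
    list(
      n_sequences = as.integer(n_sequences),
      per_position_rate = per_position_rate,
      position_weights = position_weights,
      substitution_model = match.arg(substitution_model),
      planted_variants = planted_variants,
      seed = as.integer(seed)
    ),
    class = "shm_config"
  )
}

#' Read an SHM configuration from YAML
#' @param path YAML file with [shm_config()] fields (`planted_variants` as a
#'   list of records).
#' @return An `shm_config`.
#' @export
read_shm_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$planted_variants)) {
    y$planted_variants <- do.call(
      rbind, lapply(y$planted_variants, as.data.frame)
    )
  }
  do.call(shm_config, y)
}

# similarity-weighted replacement table: weight 3 for same-class residues
.aa_classes <- list(
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "Y"),
  polar = c("S", "T", "N", "Q", "C", "G", "P"),
  positive = c("K", "R", "H"),
  negative = c("D", "E")
)

.substitute_aa <- function(from, model) {
  alts <- setdiff(AA_ALPHABET, from)
  if (model == "uniform") return(sample(alts, 1L))
  cls <- names(which(vapply(.aa_classes, function(z) from %in% z, TRUE)))
  w <- ifelse(alts %in% .aa_classes[[cls]], 3, 1)
  sample(alts, 1L, prob = w)
}

#' Simulate a somatically hypermutated repertoire
#'
#' Generates `n_sequences` copies of the germline, applies independent
#' background substitutions at the configured per-position rate, overlays the
#' planted variants at their target frequencies (planted positions are shielded
#' from background mutation so the truth table stays unambiguous), and records
#' the exact position-wise truth of every sequence. Substitutions only; the
#' sequences therefore Kabat-number positionally against the germline.
#'
#' @param germline A [germline_reference()].
#' @param config An [shm_config()].
#' @return A `synthetic_repertoire`: list with `germline`, `sequences` (named
#'   character vector) and `truth` (data frame `sequence_id`, `number`,
#'   `insertion`, `from_aa`, `to_aa`).
#' @export
simulate_repertoire <- function(germline, config) {
  stopifnot(inherits(germline, "germline_reference"), inherits(config, "shm_config"))
  set.seed(config$seed)
  res <- germline$residues
  L <- nrow(res)
  rate <- rep(config$per_position_rate, L)
  if (!is.null(config$position_weights)) {
    w <- config$position_weights[as.character(res$number)]
    w[is.na(w)] <- 0
    if (mean(w) > 0) rate <- pmin(1, config$per_position_rate * w / mean(w))
  }
  pl <- config$planted_variants
  planted_idx <- integer(0)
  if (!is.null(pl) && nrow(pl)) {
    planted_idx <- match(
      kabat_label(pl$number, pl$insertion),
      kabat_label(res$number, res$insertion)
    )
    if (anyNA(planted_idx)) stop("planted variant at a position absent from the germline")
    if (any(pl$to_aa == res$aa[planted_idx])) {
      stop("planted variant equal to the germline residue")
    }
  }
  bg_idx <- setdiff(seq_len(L), planted_idx)
  ids <- sprintf("seq%04d", seq_len(config$n_sequences))
  seqs <- character(config$n_sequences)
  truth <- vector("list", config$n_sequences)
  for (i in seq_len(config$n_sequences)) {
    aa <- res$aa
    hit <- bg_idx[stats::runif(length(bg_idx)) < rate[bg_idx]]
    for (j in hit) aa[j] <- .substitute_aa(res$aa[j], config$substitution_model)
    if (length(planted_idx)) {
      on <- stats::runif(length(planted_idx)) < pl$target_frequency
      aa[planted_idx[on]] <- pl$to_aa[on]
    }
    changed <- which(aa != res$aa)
    seqs[i] <- paste(aa, collapse = "")
    if (length(changed)) {
      truth[[i]] <- data.frame(
        sequence_id = ids[i], number = res$number[changed],
        insertion = res$insertion[changed],
        from_aa = res$aa[changed], to_aa = aa[changed],
        stringsAsFactors = FALSE
      )
    }
  }
  names(seqs) <- ids
  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(
      sequence_id = character(0), number = integer(0), insertion = character(0),
      from_aa = character(0), to_aa = character(0), stringsAsFactors = FALSE
    )
  }
  structure(
    list(germline = germline, sequences = seqs, truth = truth, config = config),
    class = "synthetic_repertoire"
  )
}

#' @export
print.synthetic_repertoire <- function(x, ...) {
  cat(
    sprintf(
      "synthetic_repertoire: %d sequences on %s (%s), %d true substitutions\n",
      length(x$sequences), x$germline$id, x$germline$chain_class, nrow(x$truth)
    )
  )
  invisible(x)
}

#' Number every repertoire sequence against its germline
#'
#' Convenience wrapper running [assign_numbering()] over a simulated
#' repertoire.
#'
#' @param rep A `synthetic_repertoire`.
#' @param ... Passed to [assign_numbering()].
#' @return List of `numbered_sequence` objects.
#' @export
number_repertoire <- function(rep, ...) {
  stopifnot(inherits(rep, "synthetic_repertoire"))
  mapply(
    function(s, id) assign_numbering(s, rep$germline, source_id = id, ...),
    rep$sequences, names(rep$sequences),
    SIMPLIFY = FALSE
  )
}

#' Write repertoire FASTA and truth table
#'
#' @param rep A `synthetic_repertoire`.
#' @param prefix Output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>_truth.tsv`.
#' @return The two paths, invisibly.
#' @export
write_repertoire <- function(rep, prefix) {
  stopifnot(inherits(rep, "synthetic_repertoire"))
  fa <- paste0(prefix, ".fasta")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(rep$sequences), fa)
  tt <- paste0(prefix, "_truth.tsv")
  utils::write.table(rep$truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, truth = tt))
}

#' Read an amino-acid FASTA as a plain character vector
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_aa_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
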