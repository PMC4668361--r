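#' Assign Kabat numbering by alignment to a pre-numbered reference
#'
#' Globally aligns an amino-acid sequence to a germline subgroup reference
#' (Needleman-Wunsch with affine gaps, BLOSUM62) and transfers the reference's
#' Kabat coordinates: residues aligned to a reference position inherit that
#' position; residues aligned to gaps in the reference receive insertion codes
#' (`A`, `B`, ...) appended to the preceding Kabat number. Residues of the
#' reference deleted in the query are simply absent from the result. The
#' procedure is deterministic for fixed inputs.
#'
#' @param sequence Amino-acid string (60-150 residues; `X` permitted).
#' @param reference A [germline_reference()].
#' @param gap_open,gap_extend Affine gap penalties (positive; defaults 10, 1).
#' @param min_score Alignment-score floor below which the sequence is rejected
#'   as unalignable.
#' @param source_id Identifier recorded in the result.
#' @return An object of class `numbered_sequence`: list with `source_id`,
#'   `chain_class`, `alignment_score` and a `residues` data frame
#'   (`number`, `insertion`, `aa`, `region`).
#' @examples
#' ref <- germline_fixture("kappa1")
#' ns <- assign_numbering(germline_sequence(ref), ref)
#' nrow(detect_deviations(ns, ref)) # 0
#' @export
assign_numbering <- function(sequence, reference, gap_open = 10, gap_extend = 1,
                             min_score = 0, source_id = "query") {
  stopifnot(inherits(reference, "germline_reference"))
  sequence <- toupper(gsub("\\s", "", sequence))
  if (!grepl("^[A-Z]*$", sequence) ||
      !all(strsplit(sequence, "")[[1]] %in% c(AA_ALPHABET, "X"))) {
    stop("invalid alphabet: sequence contains non-amino-acid characters")
  }
  n <- nchar(sequence)
  if (n < 60 || n > 150) {
    stop("sequence length ", n, " outside the supported 60-150 residue range")
  }
  refseq <- germline_sequence(reference)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sequence), Biostrings::AAString(refseq),
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  sc <- Biostrings::score(pa)
  if (sc < min_score) {
    stop(sprintf("unalignable sequence: score %.1f below floor %.1f", sc, min_score))
  }
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  refpos <- reference$residues
  out_number <- integer(0)
  out_ins <- character(0)
  out_aa <- character(0)
  ri <- 0L            # index into reference positions
  ins_run <- 0L       # consecutive insertion count after current ref position
  for (k in seq_along(qa)) {
    if (ra[k] != "-") {
      ri <- ri + 1L
      ins_run <- 0L
      if (qa[k] != "-") {
        out_number <- c(out_number, refpos$number[ri])
        out_ins <- c(out_ins, refpos$insertion[ri])
        out_aa <- c(out_aa, qa[k])
      }
    } else {
      # query residue with no reference counterpart: insertion code
      if (ri == 0L) {
        stop("insertion before the first reference position cannot be numbered")
      }
      if (refpos$insertion[ri] != "") {
        stop("insertion after an already-inserted reference position is unsupported")
      }
      ins_run <- ins_run + 1L
      if (ins_run > 26L) stop("more than 26 consecutive insertions")
      base <- refpos$number[ri]
      if (!region_of(base, kabat_region_map(reference$chain_class)) %in%
          c("CDR1", "CDR2", "CDR3")) {
        warning(
          "insertion at framework position ", base,
          " (outside canonical CDR insertion points)"
        )
      }
      out_number <- c(out_number, base)
      out_ins <- c(out_ins, LETTERS[ins_run])
      out_aa <- c(out_aa, qa[k])
    }
  }
  res <- data.frame(
    number = out_number, insertion = out_ins, aa = out_aa,
    stringsAsFactors = FALSE
  )
  res$region <- region_of(res$number, kabat_region_map(reference$chain_class))
  structure(
    list(
      source_id = source_id,
      chain_class = reference$chain_class,
      residues = res,
      alignment_score = sc
    ),
    class = "numbered_sequence"
  )
}

#' @export
print.numbered_sequence <- function(x, ...) {
  cat(
    sprintf(
      "numbered_sequence %s (%s): %d residues, alignment score %.1f\n",
      x$source_id, x$chain_class, nrow(x$residues), x$alignment_score
    )
  )
  invisible(x)
}

#' Call deviations from germline
#'
#' Position-wise comparison of a numbered sequence against its germline
#' reference: returns every Kabat position present in both where the amino
#' acids differ, in Kabat order.
#'
#' @param seq A `numbered_sequence`.
#' @param germline A `germline_reference` of the same chain class.
#' @return Data frame with columns `number`, `insertion`, `germline_aa`,
#'   `observed_aa`.
#' @export
detect_deviations <- function(seq, germline) {
  stopifnot(inherits(seq, "numbered_sequence"), inherits(germline, "germline_reference"))
  if (!identical(seq$chain_class, germline$chain_class)) {
    stop(
      "incompatible chain classes: ", seq$chain_class, " vs ",
      germline$chain_class
    )
  }
  a <- seq$residues
  g <- germline$residues
  key_a <- kabat_label(a$number, a$insertion)
  key_g <- kabat_label(g$number, g$insertion)
  i <- match(key_a, key_g)
  shared <- !is.na(i)
  diff <- shared & a$aa != g$aa[i]
  out <- data.frame(
    number = a$number[diff],
    insertion = a$insertion[diff],
    germline_aa = g$aa[i[diff]],
    observed_aa = a$aa[diff],
    stringsAsFactors = FALSE
  )
  out[kabat_order(out$number, out$insertion), , drop = FALSE]
}

#' Write numbered sequences to TSV
#'
#' One row per residue: `source_id`, `kabat_position`, `aa`, `region`.
#'
#' @param seqs A `numbered_sequence` or list of them.
#' @param path Output file.
#' @export
write_numbered <- function(seqs, path) {
  if (inherits(seqs, "numbered_sequence")) seqs <- list(seqs)
  rows <- do.call(rbind, lapply(seqs, function(s) {
    data.frame(
      source_id = s$source_id,
      kabat_position = kabat_label(s$residues$number, s$residues$insertion),
      aa = s$residues$aa,
      region = s$residues$region,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
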