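#' Kabat position labels
#'
#' Kabat coordinates address antibody variable-domain residues by a 1-based
#' number plus an optional single-letter insertion code (e.g. `100A`), so that
#' structurally equivalent residues carry the same label across antibodies.
#' Positions order by `(number, insertion)` with the code-free position sorting
#' before `A`.
#'
#' @param number Integer vector of Kabat numbers (>= 1).
#' @param insertion Character vector of insertion codes (`""` for none, or a
#'   single uppercase letter).
#' @return `kabat_label()` returns character labels such as `"4"` or `"100A"`;
#'   `kabat_order()` returns an ordering permutation.
#' @examples
#' kabat_label(c(4, 100, 100), c("", "", "A"))
#' @export
kabat_label <- function(number, insertion = "") {
  stopifnot(all(number >= 1), all(number == as.integer(number)))
  insertion <- rep_len(ifelse(is.na(insertion), "", insertion), length(number))
  bad <- insertion != "" & !grepl("^[A-Z]$", insertion)
  if (any(bad)) {
    stop("insertion codes must be empty or a single uppercase letter")
  }
  paste0(number, insertion)
}

#' @rdname kabat_label
#' @export
kabat_order <- function(number, insertion = "") {
  insertion <- rep_len(ifelse(is.na(insertion), "", insertion), length(number))
  order(number, insertion)
}

#' Parse Kabat labels back into number/insertion
#'
#' @param label Character vector such as `"100A"`.
#' @return Data frame with columns `number` and `insertion`.
#' @export
parse_kabat_label <- function(label) {
  m <- regmatches(label, regexec("^([0-9]+)([A-Z]?)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed Kabat label: ", paste(label[bad], collapse = ", "))
  data.frame(
    number = as.integer(vapply(m, `[`, "", 2L)),
    insertion = vapply(m, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

REGION_LEVELS <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")

#' Framework/CDR region boundaries in Kabat coordinates
#'
#' Returns the Kabat-convention complementarity-determining region (CDR)
#' boundaries and the framework regions (FR) tiling the remainder of the
#' domain: light chains L24-34, L50-56, L89-97; heavy chains H31-35 (with
#' insertion codes up to 35B), H50-65 and H95-102. A position with an insertion
#' code belongs to the region of its base number, so 100A falls in CDR3.
#'
#' @param chain_class One of `"heavy"`, `"kappa"`, `"lambda"` (or `"light"`,
#'   treated as kappa-style boundaries).
#' @return Data frame with columns `region`, `start`, `end` (Kabat numbers).
#' @export
kabat_region_map <- function(chain_class) {
  chain_class <- match.arg(chain_class, c("heavy", "kappa", "lambda", "light"))
  if (chain_class == "heavy") {
    bounds <- rbind(
      c(1, 30), c(31, 35), c(36, 49), c(50, 65), c(66, 94), c(95, 102), c(103, 113)
    )
  } else {
    bounds <- rbind(
      c(1, 23), c(24, 34), c(35, 49), c(50, 56), c(57, 88), c(89, 97), c(98, 107)
    )
  }
  structure(
    data.frame(
      region = REGION_LEVELS,
      start = bounds[, 1],
      end = bounds[, 2],
      stringsAsFactors = FALSE
    ),
    chain_class = chain_class,
    class = c("region_map", "data.frame")
  )
}

#' Map a Kabat position to its region label
#'
#' @param number Kabat number(s); insertion codes inherit the region of the
#'   base number and need not be supplied.
#' @param map A region map from [kabat_region_map()], or a chain class string.
#' @return Character vector of region labels.
#' @export
region_of <- function(number, map) {
  if (is.character(map) && length(map) == 1L) map <- kabat_region_map(map)
  stopifnot(inherits(map, "region_map"))
  idx <- findInterval(number, map$start)
  out <- idx < 1L | number > map$end[pmax(idx, 1L)]
  if (any(out)) {
    stop(
      "Kabat position(s) outside region-map coverage: ",
      paste(number[out], collapse = ", ")
    )
  }
  map$region[idx]
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Germline subgroup reference
#'
#' A germline reference is the unmutated subgroup sequence against which
#' somatic deviations are counted, pre-numbered in Kabat coordinates with a
#' region label per position.
#'
#' @param id Reference identifier.
#' @param chain_class `"heavy"`, `"kappa"` or `"lambda"`.
#' @param subgroup Subgroup label (e.g. `"VH3"`, `"kappa1"`).
#' @param residues Data frame with columns `number`, `insertion`, `aa`
#'   (`region` is filled from [kabat_region_map()] when absent).
#' @return An object of class `germline_reference`.
#' @export
germline_reference <- function(id, chain_class, subgroup, residues) {
  chain_class <- match.arg(chain_class, c("heavy", "kappa", "lambda"))
  stopifnot(is.data.frame(residues), all(c("number", "aa") %in% names(residues)))
  if (is.null(residues$insertion)) residues$insertion <- ""
  residues$insertion[is.na(residues$insertion)] <- ""
  o <- kabat_order(residues$number, residues$insertion)
  if (!identical(o, seq_len(nrow(residues)))) {
    stop("reference positions must be strictly increasing in Kabat order")
  }
  if (anyDuplicated(kabat_label(residues$number, residues$insertion))) {
    stop("duplicated Kabat positions in reference")
  }
  if (!all(residues$aa %in% AA_ALPHABET)) {
    stop("reference residues must be standard amino acids")
  }
  if (is.null(residues$region)) {
    residues$region <- region_of(residues$number, kabat_region_map(chain_class))
  }
  structure(
    list(
      id = id, chain_class = chain_class, subgroup = subgroup,
      residues = residues[, c("number", "insertion", "aa", "region")]
    ),
    class = "germline_reference"
  )
}

#' @export
print.germline_reference <- function(x, ...) {
  cat(
    sprintf(
      "germline_reference %s (%s, subgroup %s): %d positions %s-%s\n",
      x$id, x$chain_class, x$subgroup, nrow(x$residues),
      kabat_label(x$residues$number[1], x$residues$insertion[1]),
      kabat_label(
        x$residues$number[nrow(x$residues)],
        x$residues$insertion[nrow(x$residues)]
      )
    )
  )
  invisible(x)
}

#' Reference amino-acid sequence as a single string
#' @param ref A `germline_reference`.
#' @return Character scalar.
#' @export
germline_sequence <- function(ref) {
  stopifnot(inherits(ref, "germline_reference"))
  paste(ref$residues$aa, collapse = "")
}

#' Read / write germline reference TSV
#'
#' The on-disk format is a tab-separated table with columns `kabat_number`,
#' `insertion`, `aa`, `region`, preceded by `#`-comment metadata lines
#' (`id`, `chain_class`, `subgroup`).
#'
#' @param path File path.
#' @param ref A `germline_reference` (for writing).
#' @return `read_germline()` returns a `germline_reference`.
#' @export
read_germline <- function(path) {
  hdr <- readLines(path, n = 10L)
  meta <- function(key) {
    ln <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (!length(ln)) stop("missing '# ", key, ":' metadata line in ", path)
    sub(sprintf("^#\\s*%s:\\s*", key), "", ln[1])
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = c(insertion = "character"))
  tab$insertion[is.na(tab$insertion)] <- ""
  germline_reference(
    id = meta("id"), chain_class = meta("chain_class"),
    subgroup = meta("subgroup"),
    residues = data.frame(
      number = tab$kabat_number, insertion = tab$insertion,
      aa = tab$aa, region = tab$region, stringsAsFactors = FALSE
    )
  )
}

#' @rdname read_germline
#' @export
write_germline <- function(ref, path) {
  stopifnot(inherits(ref, "germline_reference"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(
    c(
      paste0("# id: ", ref$id),
      paste0("# chain_class: ", ref$chain_class),
      paste0("# subgroup: ", ref$subgroup),
      paste("kabat_number", "insertion", "aa", "region", sep = "\t")
    ),
    con
  )
  r <- ref$residues
  writeLines(paste(r$number, r$insertion, r$aa, r$region, sep = "\t"), con)
  invisible(path)
}

#' Built-in synthetic subgroup references
#'
#' Loads one of the synthetic subgroup-consensus references shipped with the
#' package (`"kappa1"`, `"kappa4"`, `"VH2"`, `"VH3"`). These are constructed
#' consensus-like sequences (not database alleles) carrying the canonical
#' framework identities at positions of interest (kappa M4; heavy E6, V37,
#' V48) and are intended as numbering/deviation baselines for simulated data.
#'
#' @param subgroup Subgroup name.
#' @return A `germline_reference`.
#' @export
germline_fixture <- function(subgroup = c("kappa1", "kappa4", "VH2", "VH3")) {
  subgroup <- match.arg(subgroup)
  path <- system.file(
    "extdata", sprintf("germline_%s_synthetic.tsv", tolower(subgroup)),
    package = "abdisplay"
  )
  if (path == "") stop("fixture not found for subgroup ", subgroup)
  read_germline(path)
}
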