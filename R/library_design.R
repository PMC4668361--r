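#' Canonical single-variant name
#'
#' Variants are named `<from><kabat><to>` (e.g. `M4L`, `E6Q`, `V48I`), with the
#' insertion code, when present, between the number and the target residue.
#'
#' @param from_aa,to_aa Single amino-acid letters.
#' @param number,insertion Kabat coordinate.
#' @return Character vector of names.
#' @export
variant_name <- function(from_aa, number, to_aa, insertion = "") {
  paste0(from_aa, kabat_label(number, insertion), to_aa)
}

#' Tally natural framework diversity in a numbered repertoire
#'
#' Counts, over a repertoire of Kabat-numbered sequences, every germline
#' deviation as a `(position, from, to)` observation with the number of
#' repertoire sequences carrying it. This is the mining step that turns a
#' somatically hypermutated repertoire into candidate single variants.
#'
#' @param repertoire List of `numbered_sequence` objects (all the same chain
#'   class as `germline`).
#' @param germline A [germline_reference()].
#' @return Data frame with columns `chain`, `number`, `insertion`, `from_aa`,
#'   `to_aa`, `count`, sorted by Kabat position then target residue. Empty
#'   repertoires give a zero-row frame.
#' @export
tally_natural_diversity <- function(repertoire, germline) {
  stopifnot(inherits(germline, "germline_reference"))
  chain <- if (germline$chain_class == "heavy") "heavy" else "light"
  empty <- data.frame(
    chain = character(0), number = integer(0), insertion = character(0),
    from_aa = character(0), to_aa = character(0), count = integer(0),
    stringsAsFactors = FALSE
  )
  if (!length(repertoire)) return(empty)
  devs <- lapply(repertoire, function(s) detect_deviations(s, germline))
  devs <- do.call(rbind, devs)
  if (!nrow(devs)) return(empty)
  key <- paste(devs$number, devs$insertion, devs$germline_aa, devs$observed_aa,
               sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r"))
  out <- data.frame(
    chain = chain,
    number = as.integer(parts[, 1]),
    insertion = ifelse(is.na(parts[, 2]) | parts[, 2] == "", "", parts[, 2]),
    from_aa = parts[, 3],
    to_aa = parts[, 4],
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$number, out$insertion, out$to_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Library design configuration
#'
#' Filters applied when turning observed natural diversity into a screening
#' library: framework-only positions, burial (relative solvent accessibility at
#' most `rsa_max`), paratope exclusion list, and a minimum repertoire support.
#'
#' @param rsa_max Maximum relative solvent accessibility for a position to
#'   count as buried (default 0.2, the common buried/exposed convention).
#' @param min_count Minimum number of repertoire sequences supporting a
#'   variant (default 1: any observed natural change is eligible).
#' @param excluded_positions Integer vector of Kabat numbers excluded a priori
#'   (e.g. known paratope positions).
#' @param framework_only Keep only framework-region positions (default TRUE).
#' @param missing_burial `"exclude"` treats positions without a burial
#'   annotation as exposed; `"error"` fails on them.
#' @return A `design_config` list.
#' @export
design_config <- function(rsa_max = 0.2, min_count = 1L,
                          excluded_positions = integer(0),
                          framework_only = TRUE,
                          missing_burial = c("exclude", "error")) {
  stopifnot(rsa_max > 0, rsa_max < 1, min_count >= 1)
  structure(
    list(
      rsa_max = rsa_max, min_count = as.integer(min_count),
      excluded_positions = as.integer(excluded_positions),
      framework_only = isTRUE(framework_only),
      missing_burial = match.arg(missing_burial)
    ),
    class = "design_config"
  )
}

#' Read a design configuration from YAML
#' @param path YAML file with any of the [design_config()] fields.
#' @return A `design_config`.
#' @export
read_design_config <- function(path) {
  do.call(design_config, yaml::read_yaml(path))
}

#' Design a single-variant framework library from observed diversity
#'
#' Applies the design filters to tallied natural-diversity observations:
#' retained variants lie in a framework region (when `framework_only`), at a
#' buried position (`rsa <= rsa_max`), outside the exclusion list, and are
#' supported by at least `min_count` repertoire sequences. Each observed
#' alternative amino acid at a position yields its own library member.
#'
#' @param observations Output of [tally_natural_diversity()] (rows may mix
#'   chains; the region map is chosen per row from `chain`).
#' @param burial Data frame with columns `chain`, `number`, `rsa` (fraction in
#'   0-1). Optional column `insertion`.
#' @param config A [design_config()].
#' @return Data frame of retained variants: `chain`, `number`, `insertion`,
#'   `from_aa`, `to_aa`, `support`, `name`, `filters_passed`; sorted by
#'   `(chain, position, to_aa)`. The attribute `filter_log` holds the per-
#'   observation decision table including rejected rows and the failed filter.
#' @export
design_library <- function(observations, burial, config = design_config()) {
  stopifnot(inherits(config, "design_config"))
  obs <- observations
  if (!nrow(obs)) {
    out <- obs
    out$support <- integer(0); out$name <- character(0)
    out$filters_passed <- character(0)
    out$count <- NULL
    attr(out, "filter_log") <- data.frame()
    return(out)
  }
  if (is.null(obs$insertion)) obs$insertion <- ""
  if (is.null(burial$insertion)) burial$insertion <- rep("", nrow(burial))
  bkey <- paste(burial$chain, kabat_label(burial$number, burial$insertion))
  okey <- paste(obs$chain, kabat_label(obs$number, obs$insertion))
  rsa <- burial$rsa[match(okey, bkey)]
  if (any(is.na(rsa))) {
    if (config$missing_burial == "error") {
      stop(
        "missing burial annotation for position(s): ",
        paste(unique(okey[is.na(rsa)]), collapse = ", ")
      )
    }
    rsa[is.na(rsa)] <- 1 # treated as fully exposed
  }
  region <- character(nrow(obs))
  for (ch in unique(obs$chain)) {
    map <- kabat_region_map(if (ch == "heavy") "heavy" else "kappa")
    sel <- obs$chain == ch
    region[sel] <- region_of(obs$number[sel], map)
  }
  is_fr <- startsWith(region, "FR")
  checks <- cbind(
    framework = !config$framework_only | is_fr,
    buried = rsa <= config$rsa_max,
    not_excluded = !(obs$number %in% config$excluded_positions),
    supported = obs$count >= config$min_count
  )
  keep <- rowSums(!checks) == 0L
  failed <- apply(checks, 1L, function(z) {
    paste(c("non-framework", "surface-exposed", "paratope-excluded",
            "insufficient-support")[!z], collapse = ";")
  })
  log <- data.frame(
    chain = obs$chain, position = kabat_label(obs$number, obs$insertion),
    from_aa = obs$from_aa, to_aa = obs$to_aa, count = obs$count,
    region = region, rsa = rsa, retained = keep,
    failed_filters = failed, stringsAsFactors = FALSE
  )
  out <- data.frame(
    chain = obs$chain[keep], number = obs$number[keep],
    insertion = obs$insertion[keep],
    from_aa = obs$from_aa[keep], to_aa = obs$to_aa[keep],
    support = obs$count[keep],
    name = variant_name(obs$from_aa[keep], obs$number[keep], obs$to_aa[keep],
                        obs$insertion[keep]),
    filters_passed = rep("framework;buried;not_excluded;supported", sum(keep)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chain, out$number, out$insertion, out$to_aa), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- log
  out
}

#' Read / write a variant library TSV
#'
#' Tab-separated with columns `chain`, `kabat_position`, `from_aa`, `to_aa`,
#' `support`, `name`, `filters_passed`. `read_library()` validates each stored
#' name against the name regenerated from the row's fields.
#'
#' @param variants Library data frame (from [design_library()]).
#' @param path File path.
#' @return `read_library()` returns the library data frame.
#' @export
write_library <- function(variants, path) {
  tab <- data.frame(
    chain = variants$chain,
    kabat_position = kabat_label(variants$number, variants$insertion),
    from_aa = variants$from_aa, to_aa = variants$to_aa,
    support = variants$support, name = variants$name,
    filters_passed = variants$filters_passed,
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("chain", "kabat_position", "from_aa", "to_aa", "support", "name",
            "filters_passed")
  if (!all(need %in% names(tab))) {
    stop("malformed library file: missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  pos <- tryCatch(
    parse_kabat_label(tab$kabat_position),
    error = function(e) stop("malformed library row: ", conditionMessage(e))
  )
  support <- suppressWarnings(as.integer(tab$support))
  bad <- which(is.na(support) | !tab$from_aa %in% AA_ALPHABET |
                 !tab$to_aa %in% AA_ALPHABET | tab$from_aa == tab$to_aa)
  if (length(bad)) {
    stop("malformed library row at line ", bad[1] + 1L)
  }
  out <- data.frame(
    chain = tab$chain, number = pos$number, insertion = pos$insertion,
    from_aa = tab$from_aa, to_aa = tab$to_aa, support = support,
    name = tab$name, filters_passed = tab$filters_passed,
    stringsAsFactors = FALSE
  )
  regen <- variant_name(out$from_aa, out$number, out$to_aa, out$insertion)
  mism <- which(regen != out$name)
  if (length(mism)) {
    stop("library row ", mism[1] + 1L, ": stored name '", out$name[mism[1]],
         "' does not match fields ('", regen[mism[1]], "')")
  }
  out
}
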