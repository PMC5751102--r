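# Dataset-level characterizations of epitope regions: amino-acid
# composition, physico-chemical property tests, Kabat-CDR epitope
# classification, and the substitution/insertion census of an immunogenic
# antibody against aligned background (human) antibodies.

#' Amino-acid composition of epitope vs. surface non-immunogenic regions
#'
#' Pools residue counts over a set of classified structures and normalizes
#' within each class, giving per-amino-acid frequencies on epitope regions
#' and on surface non-immunogenic regions, plus their difference
#' (epitope minus surface).
#'
#' @param classmaps A `residue_class_map` or list of them.
#' @return Data frame of class `region_composition`: aa1, epitope_freq,
#'   surface_freq, difference; 20 rows, each frequency column summing to 1.
#' @export
region_composition <- function(classmaps) {
  if (inherits(classmaps, "residue_class_map")) classmaps <- list(classmaps)
  all <- do.call(rbind, lapply(classmaps, function(m) {
    as.data.frame(m)[, c("aa3", "class")]
  }))
  all$aa1 <- AA3_TO_AA1[all$aa3]
  all <- all[!is.na(all$aa1), , drop = FALSE]
  aa <- unname(AA3_TO_AA1)
  count <- function(cls) {
    sub <- all$aa1[all$class == cls]
    if (!length(sub)) stop("no residues of class ", cls,
                           "; composition undefined")
    tab <- table(factor(sub, levels = aa))
    as.numeric(tab) / length(sub)
  }
  out <- data.frame(aa1 = aa,
                    epitope_freq = count("EPITOPE"),
                    surface_freq = count("SURFACE_NONIMMUNOGENIC"),
                    stringsAsFactors = FALSE)
  out$difference <- out$epitope_freq - out$surface_freq
  class(out) <- c("region_composition", "data.frame")
  out
}

#' Two-tailed Welch t-test between region property values
#'
#' Compares the per-residue values of one AAindex property over an epitope
#' region of the immunogenic antibody with the values over the
#' corresponding background-antibody region, using the unequal-variance
#' (Welch) two-sample t-test. When both groups are constant the p-value is
#' 1 for equal means and 0 otherwise.
#'
#' @param iab_values Numeric vector (>= 2 values) from the iAb region.
#' @param background_values Numeric vector (>= 2 values) from the
#'   background region.
#' @param index_id Optional AAindex accession recorded in the result.
#' @return List of class `index_test_result`: index_id, mean_iab,
#'   mean_background, p_value, statistic, df.
#' @export
aaindex_region_test <- function(iab_values, background_values,
                                index_id = NA_character_) {
  if (length(iab_values) < 2L || length(background_values) < 2L) {
    stop("each group needs at least 2 values")
  }
  m1 <- mean(iab_values); m2 <- mean(background_values)
  if (stats::var(iab_values) == 0 && stats::var(background_values) == 0) {
    p <- if (isTRUE(all.equal(m1, m2))) 1 else 0
    tt <- list(statistic = c(t = if (p == 1) 0 else Inf), parameter = c(df = NA))
  } else {
    tt <- stats::t.test(iab_values, background_values,
                        alternative = "two.sided", var.equal = FALSE)
    p <- tt$p.value
  }
  structure(
    list(index_id = index_id, mean_iab = m1, mean_background = m2,
         p_value = p, statistic = unname(tt$statistic),
         df = unname(tt$parameter)),
    class = "index_test_result"
  )
}

#' @export
print.index_test_result <- function(x, ...) {
  cat(sprintf("%s: mean iAb %.4f vs background %.4f, p = %.4g\n",
              if (is.na(x$index_id)) "index test" else x$index_id,
              x$mean_iab, x$mean_background, x$p_value))
  invisible(x)
}

#' CDR membership under Kabat numbering
#'
#' Complementarity-determining regions are, in Kabat numbering: heavy chain
#' 31-35b, 50-65, 95-102; light chain 24-34, 50-56, 89-97. Insertion
#' letters inside a numeric range (e.g. H100A) are CDR; the 35b upper bound
#' means positions 35, 35A and 35B.
#'
#' @param chain_type `"H"` or `"L"`.
#' @param number Kabat position number(s).
#' @param letter Insertion letter(s), `""` for none.
#' @return Logical vector.
#' @export
kabat_is_cdr <- function(chain_type, number, letter = "") {
  n <- length(number)
  chain_type <- rep_len(toupper(chain_type), n)
  letter <- rep_len(toupper(ifelse(is.na(letter), "", letter)), n)
  number <- as.integer(number)
  heavy <- (number >= 31L & number <= 34L) |
    (number == 35L & letter %in% c("", "A", "B")) |
    (number >= 50L & number <= 65L) |
    (number >= 95L & number <= 102L)
  light <- (number >= 24L & number <= 34L) |
    (number >= 50L & number <= 56L) |
    (number >= 89L & number <= 97L)
  ifelse(chain_type == "H", heavy, ifelse(chain_type == "L", light, NA))
}

#' Read a Kabat annotation table
#'
#' TSV with columns chain, resnum, icode, kabat_label and optionally
#' is_cdr. Labels look like `"H31"`, `"H100A"`, `"L27"`; when is_cdr is
#' absent it is derived from the label via [kabat_is_cdr()].
#'
#' @param path TSV file path.
#' @return Data frame with an added `key` column and logical `is_cdr`.
#' @export
read_kabat_annotation <- function(path) {
  k <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  k$resnum <- as.integer(k$resnum)
  k$icode[is.na(k$icode)] <- ""
  k$key <- residue_key(k$chain, k$resnum, k$icode)
  lab <- toupper(k$kabat_label)
  ct <- substr(lab, 1L, 1L)
  num <- as.integer(gsub("[^0-9]", "", lab))
  let <- gsub("^[HL][0-9]+", "", lab)
  if (is.null(k$is_cdr)) {
    k$is_cdr <- kabat_is_cdr(ct, num, let)
  } else {
    k$is_cdr <- as.logical(k$is_cdr) | toupper(k$is_cdr) %in% c("TRUE", "1", "YES")
  }
  k
}

#' Classify an epitope region as CDR-based
#'
#' A region is CDR-based when more than half of its residues are CDR
#' residues (`mode = "region_fraction"`, the default reading). The
#' alternative reading — the region covers more than half of all CDR
#' residues — is available as `mode = "cdr_coverage"`.
#'
#' @param region Character vector of residue keys forming one epitope
#'   region.
#' @param kabat Data frame with columns `key` and `is_cdr` covering every
#'   region residue (see [read_kabat_annotation()]).
#' @param mode `"region_fraction"` or `"cdr_coverage"`.
#' @return Logical flag.
#' @export
classify_cdr_epitope <- function(region, kabat,
                                 mode = c("region_fraction", "cdr_coverage")) {
  mode <- match.arg(mode)
  i <- match(region, kabat$key)
  if (anyNA(i)) {
    stop("unannotated residue(s): ",
         paste(region[is.na(i)], collapse = ", "))
  }
  in_cdr <- kabat$is_cdr[i]
  if (mode == "region_fraction") {
    sum(in_cdr) / length(region) > 0.5
  } else {
    total_cdr <- sum(kabat$is_cdr)
    if (total_cdr == 0L) return(FALSE)
    sum(in_cdr) / total_cdr > 0.5
  }
}

#' Read a gapped FASTA alignment
#'
#' @param path FASTA file; sequences may contain `-` gaps and must share
#'   one alignment length.
#' @return Named character vector of aligned sequences.
#' @export
read_gapped_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    s <- Biostrings::readBStringSet(path)
    seqs <- stats::setNames(as.character(s), names(s))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    id <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], id[!hdr]), paste0, "", collapse = "")
    names(seqs) <- sub("^>\\s*", "", lines[hdr])
  }
  seqs <- toupper(gsub("\\s", "", seqs))
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned sequences must all have the same length")
  }
  seqs
}

#' Substitution/insertion census of an iAb against background antibodies
#'
#' For each epitope alignment column, the most frequent residue among the
#' background antibodies is compared with the iAb residue. A column in
#' which gaps make up a strict majority of the background sequences while
#' the iAb carries a residue is an insertion (INSERTED). Otherwise the
#' modal background residue is the most frequent non-gap character (ties
#' broken alphabetically) and the position is SAME when the iAb residue
#' equals it, SUBSTITUTED when it differs.
#'
#' @param alignment Named character vector of equal-length gapped sequences
#'   (see [read_gapped_fasta()]); must contain `iab_id`.
#' @param iab_id Name of the immunogenic-antibody sequence; all other
#'   sequences are background.
#' @param epitope_columns Integer vector of 1-based alignment columns that
#'   map to epitope residues.
#' @return Data frame of class `position_census`: column, iab_residue,
#'   modal_residue, modal_freq (fraction of background sequences), status;
#'   with attribute `summary` (named counts SAME/SUBSTITUTED/INSERTED).
#' @export
substitution_insertion_census <- function(alignment, iab_id, epitope_columns) {
  if (!(iab_id %in% names(alignment))) {
    stop("iab_id '", iab_id, "' not found in alignment")
  }
  bg <- alignment[setdiff(names(alignment), iab_id)]
  if (!length(bg)) stop("alignment has no background sequences")
  width <- nchar(alignment[[iab_id]])
  epitope_columns <- as.integer(epitope_columns)
  if (any(epitope_columns < 1L | epitope_columns > width)) {
    stop("epitope columns outside alignment width")
  }
  bgm <- do.call(rbind, strsplit(unname(bg), ""))
  iab <- strsplit(alignment[[iab_id]], "")[[1L]]

  rows <- lapply(epitope_columns, function(col) {
    chars <- bgm[, col]
    n_gap <- sum(chars == "-")
    if (n_gap > length(chars) / 2 && iab[col] != "-") {
      return(data.frame(column = col, iab_residue = iab[col],
                        modal_residue = "-", modal_freq = n_gap / length(chars),
                        status = "INSERTED", stringsAsFactors = FALSE))
    }
    nong <- chars[chars != "-"]
    if (!length(nong)) {  # all-gap background with gapped iAb
      return(data.frame(column = col, iab_residue = iab[col],
                        modal_residue = "-", modal_freq = 1,
                        status = if (iab[col] == "-") "SAME" else "INSERTED",
                        stringsAsFactors = FALSE))
    }
    tab <- table(nong)
    modal <- sort(names(tab)[tab == max(tab)])[1L]  # alphabetical tie-break
    data.frame(column = col, iab_residue = iab[col], modal_residue = modal,
               modal_freq = as.numeric(tab[modal]) / length(chars),
               status = if (iab[col] == modal) "SAME" else "SUBSTITUTED",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("position_census", "data.frame")
  attr(out, "summary") <- c(
    SAME = sum(out$status == "SAME"),
    SUBSTITUTED = sum(out$status == "SUBSTITUTED"),
    INSERTED = sum(out$status == "INSERTED"))
  out
}
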