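#' Read phased genotypes from a VCF file
#'
#' Reads a VCF whose GT fields are all phased (`|` separator, ploidy 2) into
#' a [haplo_matrix()].  Multi-allelic sites are preserved; allele codes are
#' the VCF allele indices (0 = REF).  Missing or unphased genotypes are
#' rejected with an error naming the first offending record: the downstream
#' frequency computations require complete data.
#'
#' @param path path to a VCF (optionally bgzipped) file.
#' @param labels_path optional path to a two-column TSV
#'   (individual id, population id) of population labels.
#' @return A [haplo_matrix()] with one column per VCF site and REF/ALT
#'   strings retained in the marker table.
#' @export
read_phased_vcf <- function(path, labels_path = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  if (anyDuplicated(samples)) {
    stop("duplicate individual id in VCF: ",
         samples[duplicated(samples)][1L], call. = FALSE)
  }
  site_name <- paste0(fix[, "CHROM"], ":", fix[, "POS"])

  bad <- which(is.na(gt) | gt == "." | grepl(".", gt, fixed = TRUE))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(gt))
    stop("missing genotype at ", site_name[i[1L]], " for sample ",
         samples[i[2L]], call. = FALSE)
  }
  bad <- which(grepl("/", gt, fixed = TRUE))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(gt))
    stop("unphased genotype '", gt[bad[1L]], "' at ", site_name[i[1L]],
         " for sample ", samples[i[2L]], call. = FALSE)
  }
  bad <- which(!grepl("^[0-9]+\\|[0-9]+$", gt))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(gt))
    stop("genotype '", gt[bad[1L]], "' at ", site_name[i[1L]],
         " is not a phased diploid call", call. = FALSE)
  }

  l <- nrow(gt); n <- ncol(gt)
  a1 <- matrix(as.integer(sub("\\|.*", "", gt)), nrow = l)
  a2 <- matrix(as.integer(sub(".*\\|", "", gt)), nrow = l)
  # rows 2i-1, 2i hold the two chromosomes of individual i
  alleles <- matrix(0L, nrow = 2L * n, ncol = l)
  alleles[seq(1L, 2L * n, by = 2L), ] <- t(a1)
  alleles[seq(2L, 2L * n, by = 2L), ] <- t(a2)

  alt <- fix[, "ALT"]
  n_alt <- ifelse(is.na(alt) | alt == ".", 0L,
                  lengths(strsplit(alt, ",", fixed = TRUE)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- site_name[is.na(ids) | ids == "."]
  markers <- data.frame(
    id = ids, chrom = fix[, "CHROM"], pos_bp = as.integer(fix[, "POS"]),
    pos_cm = NA_real_, n_alleles = pmax(1L + n_alt, 1L),
    ref = fix[, "REF"], alt = alt, stringsAsFactors = FALSE)

  labels <- if (!is.null(labels_path)) read_labels(labels_path) else NULL
  haplo_matrix(alleles, markers, samples, labels)
}

#' Read a plain haplotype allele-code table
#'
#' Reads a whitespace-separated `2n x l` table of integer allele codes (two
#' consecutive rows per individual) together with a marker metadata sidecar.
#'
#' @param path path to the allele-code table.  Rows may optionally start with
#'   a chromosome id column named by the individual; by default rows are
#'   anonymous and individuals are numbered `ind1, ind2, ...`.
#' @param markers_path path to a TSV with header columns
#'   `id chrom pos_bp pos_cm n_alleles` (`pos_cm` may be `.` or `NA`).
#' @param labels_path optional labels TSV as in [read_phased_vcf()].
#' @return A [haplo_matrix()].
#' @export
read_haplo_table <- function(path, markers_path, labels_path = NULL) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  mk <- utils::read.table(markers_path, header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", "."))
  a <- as.matrix(tab)
  if (!all(grepl("^[0-9]+$", a))) {
    bad <- which(!grepl("^[0-9]+$", a))[1L]
    stop("non-integer allele code '", a[bad], "' in ", path, call. = FALSE)
  }
  storage.mode(a) <- "integer"
  dimnames(a) <- NULL
  if (nrow(a) %% 2L != 0L) {
    stop("haplotype table has an odd number of chromosome rows (",
         nrow(a), ")", call. = FALSE)
  }
  individuals <- paste0("ind", seq_len(nrow(a) / 2L))
  if (!"pos_cm" %in% names(mk)) mk$pos_cm <- NA_real_
  labels <- if (!is.null(labels_path)) read_labels(labels_path) else NULL
  if (!is.null(labels) && length(labels) == length(individuals) &&
      all(!names(labels) %in% individuals)) {
    # labels file enumerates ids for anonymous rows, adopt them in file order
    individuals <- names(labels)
  }
  haplo_matrix(a, mk, individuals, labels)
}

#' Write a haplotype matrix as a plain table plus sidecars
#'
#' Inverse of [read_haplo_table()]: writes the allele-code table, the marker
#' metadata sidecar and, when labels are present, a labels TSV.
#'
#' @param x a [haplo_matrix()].
#' @param path output path for the allele-code table.
#' @param markers_path output path for the marker sidecar.
#' @param labels_path optional output path for the labels TSV.
#' @return Invisibly, `x`.
#' @export
write_haplo_table <- function(x, path, markers_path, labels_path = NULL) {
  stopifnot(inherits(x, "haplo_matrix"))
  utils::write.table(x$alleles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  mk <- x$markers[, intersect(c("id", "chrom", "pos_bp", "pos_cm",
                                "n_alleles"), names(x$markers))]
  utils::write.table(mk, markers_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(labels_path) && !is.null(x$labels)) {
    utils::write.table(
      data.frame(individual = names(x$labels), population = x$labels),
      labels_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(x)
}

#' Read population labels
#'
#' @param path two-column whitespace/TSV file: individual id, population id.
#'   A header line is skipped if its first field is `individual` or
#'   `individual_id`.
#' @return Named character vector mapping individual id to population id.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (tolower(tab[1L, 1L]) %in% c("individual", "individual_id", "id")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  if (ncol(tab) < 2L) stop("labels file needs two columns", call. = FALSE)
  if (anyDuplicated(tab[[1L]])) {
    stop("duplicate individual id in labels: ",
         tab[[1L]][duplicated(tab[[1L]])][1L], call. = FALSE)
  }
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Read a genetic map
#'
#' @param path TSV with header columns `chrom pos_bp pos_cm`.
#' @return Data frame with those columns.
#' @export
read_genetic_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos_bp", "pos_cm") %in% names(m)))
  m
}

#' Attach genetic-map positions to markers
#'
#' Fills `markers$pos_cm` by linear interpolation of the genetic map within
#' each chromosome (positions beyond the map ends are clamped to the end
#' values).
#'
#' @param x a [haplo_matrix()].
#' @param map a genetic map as returned by [read_genetic_map()].
#' @return `x` with `pos_cm` populated.
#' @export
attach_genetic_map <- function(x, map) {
  stopifnot(inherits(x, "haplo_matrix"))
  for (ch in unique(x$markers$chrom)) {
    sel <- x$markers$chrom == ch
    msel <- map$chrom == ch
    if (!any(msel)) stop("genetic map has no entries for chromosome ", ch,
                         call. = FALSE)
    x$markers$pos_cm[sel] <- stats::approx(
      map$pos_bp[msel], map$pos_cm[msel], xout = x$markers$pos_bp[sel],
      rule = 2, ties = "ordered")$y
  }
  x
}
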