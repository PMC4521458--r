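#' Write or read a haplotype coding file
#'
#' The haplotype coding file records the correspondence between haplotype
#' loci and the initial markers: one TSV row per haplotype-allele
#' (`locus_id, chrom, member marker ids, constituent allele tuple, code`),
#' preceded by `#`-prefixed header lines carrying the window specification,
#' the GIA threshold, the training individuals, the populations, and the
#' marker metadata.  The format is plain text so coding files can be
#' inspected and diffed.  `read_haplomap(write_haplomap(m, f))` reproduces
#' `m` field for field.
#'
#' @param map a `haplo_map` from [haplopop()].
#' @param path output (input) file path.
#' @return `write_haplomap` invisibly returns `map`; `read_haplomap` returns
#'   a `haplo_map`.
#' @export
write_haplomap <- function(map, path) {
  stopifnot(inherits(map, "haplo_map"))
  members <- unlist(lapply(map$loci, `[[`, "members"))
  if (!identical(sort(members), seq_len(nrow(map$markers)))) {
    stop("refusing to write: loci do not partition the markers",
         call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) format(x, digits = 17)
  writeLines(c(
    "#HAPLOPOP_MAP\t1",
    paste0("#WINDOW\t", map$window$mode, "\t", num(map$window$size)),
    paste0("#GIA_THRESHOLD\t", num(map$gia_threshold)),
    paste0("#MAX_ALLELES\t", num(map$max_alleles)),
    paste0("#TRAINING\t", paste(map$training, collapse = ",")),
    paste0("#POPULATIONS\t", paste(map$populations, collapse = ",")),
    paste0("#OBJECTIVE\t", num(map$objective[["genotype"]]), "\t",
           num(map$objective[["haplotype"]])),
    paste0("#N_MERGES\t", map$n_merges)), con)
  mk <- map$markers
  writeLines(paste("#MARKER", mk$id, mk$chrom, mk$pos_bp,
                   ifelse(is.na(mk$pos_cm), ".", num(mk$pos_cm)),
                   mk$n_alleles, sep = "\t"), con)
  writeLines("locus_id\tchrom\tmarker_ids\tallele_tuple\tcode", con)
  for (k in seq_along(map$loci)) {
    lc <- map$loci[[k]]
    writeLines(paste(sprintf("L%04d", k), lc$chrom,
                     paste(lc$marker_ids, collapse = ","),
                     names(lc$coding), lc$coding, sep = "\t"), con)
  }
  invisible(map)
}

#' @rdname write_haplomap
#' @export
read_haplomap <- function(path) {
  lines <- readLines(path)
  fail <- function(i, msg) {
    stop("malformed haplotype map file at line ", i, ": ", msg,
         call. = FALSE)
  }
  if (!length(lines) || !startsWith(lines[1L], "#HAPLOPOP_MAP")) {
    fail(1L, "missing #HAPLOPOP_MAP header")
  }
  hdr <- list()
  markers <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    key <- sub("^#", "", f[1L])
    if (key == "MARKER") {
      if (length(f) != 6L) fail(i, "#MARKER needs 5 fields")
      markers[[length(markers) + 1L]] <- f[-1L]
    } else {
      hdr[[key]] <- f[-1L]
    }
    i <- i + 1L
  }
  for (key in c("WINDOW", "GIA_THRESHOLD", "TRAINING", "POPULATIONS")) {
    if (is.null(hdr[[key]])) fail(i, paste0("missing #", key, " header"))
  }
  if (!length(markers)) fail(i, "no #MARKER lines")
  mk <- do.call(rbind, markers)
  markers <- data.frame(
    id = mk[, 1L], chrom = mk[, 2L], pos_bp = as.integer(mk[, 3L]),
    pos_cm = suppressWarnings(as.numeric(ifelse(mk[, 4L] == ".", NA, mk[, 4L]))),
    n_alleles = as.integer(mk[, 5L]), stringsAsFactors = FALSE)
  if (anyNA(markers$pos_bp) || anyNA(markers$n_alleles)) {
    fail(i, "non-numeric marker position or allele count")
  }

  if (i > length(lines) || !identical(lines[i],
      "locus_id\tchrom\tmarker_ids\tallele_tuple\tcode")) {
    fail(i, "missing locus table header")
  }
  loci <- list()
  order_seen <- character()
  for (r in seq(i + 1L, length.out = length(lines) - i)) {
    f <- strsplit(lines[r], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 5L) fail(r, "expected 5 tab-separated fields")
    id <- f[1L]
    code <- suppressWarnings(as.integer(f[5L]))
    if (is.na(code)) fail(r, "non-integer haplotype-allele code")
    if (!id %in% order_seen) {
      order_seen <- c(order_seen, id)
      mem <- match(strsplit(f[3L], ",", fixed = TRUE)[[1L]], markers$id)
      if (anyNA(mem)) fail(r, "unknown member marker id")
      loci[[id]] <- list(marker_ids = markers$id[mem], members = mem,
                         chrom = f[2L], coding = integer(), n_alleles = 0L)
    }
    loci[[id]]$coding[[f[4L]]] <- code
  }
  loci <- unname(loci[order_seen])
  loci <- lapply(loci, function(lc) {
    if (!identical(sort(unname(lc$coding)),
                   seq(0L, length.out = length(lc$coding)))) {
      stop("malformed haplotype map file: codes of locus on markers ",
           paste(lc$marker_ids, collapse = ","),
           " are not 0..n_alleles-1", call. = FALSE)
    }
    lc$n_alleles <- length(lc$coding)
    lc
  })

  win <- window_spec(hdr$WINDOW[1L], as.numeric(hdr$WINDOW[2L]))
  obj <- if (!is.null(hdr$OBJECTIVE)) {
    c(genotype = as.numeric(hdr$OBJECTIVE[1L]),
      haplotype = as.numeric(hdr$OBJECTIVE[2L]))
  } else c(genotype = NA_real_, haplotype = NA_real_)
  map <- structure(list(
    window = win,
    gia_threshold = as.numeric(hdr$GIA_THRESHOLD[1L]),
    max_alleles = if (is.null(hdr$MAX_ALLELES)) 0 else
      as.numeric(hdr$MAX_ALLELES[1L]),
    loci = loci, markers = markers,
    training = strsplit(hdr$TRAINING[1L], ",", fixed = TRUE)[[1L]],
    populations = strsplit(hdr$POPULATIONS[1L], ",", fixed = TRUE)[[1L]],
    objective = obj,
    n_merges = if (is.null(hdr$N_MERGES)) NA_integer_ else
      as.integer(hdr$N_MERGES[1L])), class = "haplo_map")
  members <- unlist(lapply(map$loci, `[[`, "members"))
  if (!identical(sort(members), seq_len(nrow(map$markers)))) {
    stop("malformed haplotype map file: loci do not partition the markers",
         call. = FALSE)
  }
  map
}
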