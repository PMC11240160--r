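## File formats. Summary statistics travel in the tab-separated `.ma`
## dialect (SNP A1 A2 freq b se p N, optional INFO and CHR/POS columns);
## landmark files are an index,x,y CSV with a JSON sidecar carrying the
## pixel spacing. Positions are 1-based in summary statistics, 0-based
## half-open in BED gene files; conversion lives in annotateNearestGene.

.maHeader <- c(SNP = "snp", A1 = "ea", A2 = "oa", freq = "eaf", b = "beta",
               se = "se", p = "p", N = "n")
.maOptional <- c(INFO = "info", CHR = "chr", POS = "pos")

#' Read a summary-statistic table
#'
#' Reads a tab-separated association file with mandatory columns SNP A1 A2
#' freq b se p N and optional INFO, CHR, POS. Rows failing validation are
#' rejected with their line numbers.
#'
#' @param path file path.
#' @return data.frame with columns snp, ea, oa, eaf, beta, se, p, n and,
#'   when present, info, chr, pos.
#' @export
readSumstats <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  miss <- setdiff(names(.maHeader), names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  cols <- c(.maHeader, .maOptional[names(.maOptional) %in% names(raw)])
  out <- raw[names(cols)]
  names(out) <- unname(cols)
  numcols <- setdiff(names(out), c("snp", "ea", "oa", "chr"))
  for (cn in numcols) {
    val <- suppressWarnings(as.numeric(out[[cn]]))
    bad <- which(is.na(val) & !is.na(out[[cn]]) & out[[cn]] != "NA")
    if (length(bad))
      stop("non-numeric ", cn, " on line ", bad[1] + 1L)
    out[[cn]] <- val
  }
  badf <- which(!is.na(out$eaf) & (out$eaf <= 0 | out$eaf >= 1))
  if (length(badf))
    stop("allele frequency outside (0, 1) on line ", badf[1] + 1L)
  bads <- which(!is.na(out$se) & out$se <= 0)
  if (length(bads))
    stop("non-positive standard error on line ", bads[1] + 1L)
  if ("chr" %in% names(out))
    out$chr <- utils::type.convert(out$chr, as.is = TRUE)
  out
}

#' Write a summary-statistic table
#'
#' Writes the `.ma` dialect read by \code{\link{readSumstats}}; numeric
#' values are written at full precision so a write-read round trip is the
#' identity. The table is schema-validated before writing.
#'
#' @param table data.frame with columns snp, ea, oa, eaf, beta, se, p, n
#'   and optionally info, chr, pos.
#' @param path destination.
#' @return invisibly, the path.
#' @export
writeSumstats <- function(table, path) {
  need <- unname(.maHeader)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(table$eaf <= 0 | table$eaf >= 1))
    stop("refusing to write allele frequencies outside (0, 1)")
  if (any(table$se <= 0)) stop("refusing to write non-positive SEs")
  inv <- c(.maHeader, .maOptional)
  keep <- inv[unname(inv) %in% names(table)]
  out <- table[unname(keep)]
  names(out) <- names(keep)
  fmt <- function(x) if (is.numeric(x)) formatC(x, digits = 17,
                                                format = "g") else x
  out[] <- lapply(out, fmt)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a landmark annotation
#'
#' The points file is a CSV with columns index (1-based), x, y in pixel
#' coordinates; a JSON sidecar (same path plus ".json") records
#' pixel_spacing_x_mm and pixel_spacing_y_mm.
#'
#' @param annotation a \linkS4class{ShapeAnnotation}.
#' @param path CSV destination.
#' @return invisibly, the path.
#' @export
writeShapeAnnotation <- function(annotation, path) {
  pts <- landmarks(annotation)
  df <- data.frame(index = seq_len(nrow(pts)),
                   x = formatC(pts[, 1], digits = 17, format = "g"),
                   y = formatC(pts[, 2], digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(pixel_spacing_x_mm = annotation@spacingX,
                            pixel_spacing_y_mm = annotation@spacingY),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeShapeAnnotation
#' @param sidecar path of the spacing JSON (default path + ".json").
#' @return for the reader, a \linkS4class{ShapeAnnotation}.
#' @export
readShapeAnnotation <- function(path, sidecar = paste0(path, ".json")) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(sidecar)
  pts <- unname(as.matrix(df[order(df$index), c("x", "y")]))
  new("ShapeAnnotation", points = pts,
      spacingX = as.numeric(meta$pixel_spacing_x_mm),
      spacingY = as.numeric(meta$pixel_spacing_y_mm))
}

#' Read a BED gene file
#'
#' Tab-separated, no header: chrom, start (0-based), end (exclusive), name.
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end, name.
#' @export
readGenesBed <- function(path) {
  g <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(g) < 4L) stop("BED file needs chrom, start, end, name")
  g <- g[1:4]
  names(g) <- c("chrom", "start", "end", "name")
  if (any(g$end <= g$start)) stop("BED intervals must satisfy end > start")
  g
}

#' Write cohort, panel and architecture ground truth to disk
#'
#' The cohort goes to a TSV (covariates, phenotypes, events, discovery
#' flag), the panel to a dosage TSV (variants as columns), and the causal
#' architecture to a truth JSON.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param path destination TSV.
#' @return invisibly, the path.
#' @export
writeCohortTsv <- function(cohort, path) {
  df <- cbind(id = seq_len(nIndividuals(cohort)), covariates(cohort),
              phenotypes(cohort), fractureEvents(cohort),
              discovery = as.integer(discoveryFlag(cohort)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortTsv
#' @param panel a \linkS4class{ReferencePanel}.
#' @export
writePanelTsv <- function(panel, path) {
  dos <- dosages(panel)
  utils::write.table(cbind(id = seq_len(nrow(dos)), as.data.frame(dos)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortTsv
#' @param arch a \linkS4class{CausalArchitecture}.
#' @export
writeArchitectureJson <- function(arch, path) {
  jsonlite::write_json(list(
    variant_ids = arch@variantIds,
    fnw_effects = as.list(arch@fnwEffects),
    bmd_effects = as.list(arch@bmdEffects),
    shared_inverse_ids = arch@sharedInverseIds,
    shared_positive_ids = arch@sharedPositiveIds,
    target_fnw_variance = arch@targetFnwVariance,
    log_hr = lapply(arch@logHr, as.list)), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
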