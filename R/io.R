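# Readers and writers for the bundle's plain-text interchange formats:
# expression TSV (gene_id + <cellline>__t<hours> columns), SF2 TSV, per-gene
# heat TSV, weighted edge-list TSV, GMT gene sets, truth/manifest JSON.

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read a time-course expression matrix as TSV
#'
#' Columns are `gene_id` then one column per sample named
#' `<cellline>__t<hours>`.
#'
#' @param tce a \linkS4class{TimeCourseExperiment}.
#' @param path file path.
#' @return `readExpressionTSV` returns a
#'   \linkS4class{TimeCourseExperiment}.
#' @export
writeExpressionTSV <- function(tce, path) {
  cd <- SummarizedExperiment::colData(tce)
  m <- SummarizedExperiment::assay(tce, "exprs")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  colnames(df)[-1] <- paste0(cd$cell_line, "__t", cd$hour)
  writeTSV(df, path)
  invisible(path)
}

#' @rdname writeExpressionTSV
#' @export
readExpressionTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  parts <- strsplit(colnames(m), "__t", fixed = TRUE)
  TimeCourseExperiment(m,
                       cellLine = vapply(parts, `[`, "", 1),
                       hour = as.numeric(vapply(parts, `[`, "", 2)))
}

#' Write / read an SF2 table as TSV (columns cell_line, sf2)
#'
#' @param sf2 a \linkS4class{RadiosensitivityTable}.
#' @param path file path.
#' @export
writeSF2TSV <- function(sf2, path) {
  writeTSV(data.frame(cell_line = sf2@cellLine, sf2 = sf2@sf2), path)
  invisible(path)
}

#' @rdname writeSF2TSV
#' @export
readSF2TSV <- function(path) {
  df <- utils::read.delim(path)
  radiosensitivityTable(df$cell_line, df$sf2)
}

writeHeatTSV <- function(heat, path) {
  writeTSV(data.frame(gene_id = names(heat), heat = unname(heat)), path)
  invisible(path)
}

readHeatTSV <- function(path) {
  df <- utils::read.delim(path)
  setNames(df$heat, df$gene_id)
}

writeEdgeTSV <- function(edges, path) {
  writeTSV(data.frame(gene_a = edges$from, gene_b = edges$to,
                      weight = edges$weight), path)
  invisible(path)
}

readEdgeTSV <- function(path) {
  df <- utils::read.delim(path)
  data.frame(from = as.character(df$gene_a), to = as.character(df$gene_b),
             weight = df$weight, stringsAsFactors = FALSE)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional descriptions (defaults to the names).
#' @return `readGMT` returns a named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  sets
}

#' @rdname readGMT
#' @export
writeGMT <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
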