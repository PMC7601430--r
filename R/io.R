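#' Read and write genotype panels as TSV
#'
#' The genotype file has the animal id in the first column and one column
#' per SNP with dosages 0/1/2 or NA; the companion map file has columns
#' `snp`, `chrom`, `pos_bp` (1-based).
#'
#' @param geno_file,map_file paths to the two TSV files.
#' @return `read_genotypes` returns a `genotype_panel`.
#' @export
read_genotypes <- function(geno_file, map_file) {
  g <- utils::read.delim(geno_file, stringsAsFactors = FALSE,
                         check.names = FALSE)
  ids <- as.character(g[[1]])
  geno <- as.matrix(g[, -1, drop = FALSE])
  storage.mode(geno) <- "integer"
  rownames(geno) <- ids
  map <- utils::read.delim(map_file, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  if (!identical(map$snp, colnames(geno)))
    stop("map SNPs do not match genotype columns")
  structure(list(geno = geno, map = map), class = "genotype_panel")
}

#' @param panel a `genotype_panel`.
#' @rdname read_genotypes
#' @export
write_genotypes <- function(panel, geno_file, map_file) {
  df <- data.frame(animal = rownames(panel$geno), panel$geno,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, geno_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(panel$map, map_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(geno_file)
}

#' Write / read a dense matrix as TSV with an id header
#' @param m matrix with dimnames.
#' @param file path.
#' @export
write_matrix_tsv <- function(m, file) {
  df <- data.frame(id = rownames(m), as.matrix(m), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Sparse symmetric matrices as (i, j, value) triplet text files
#'
#' Stores the lower triangle (including the diagonal) of a sparse symmetric
#' matrix with 1-based indices and an id lookup, one triplet per line.
#'
#' @param m a sparse symmetric `Matrix`.
#' @param file path.
#' @export
write_triplet <- function(m, file) {
  tm <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  keep <- tm@i >= tm@j
  df <- data.frame(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L,
                   value = tm@x[keep])
  con <- file(file, "w")
  writeLines(paste0("#ids\t", paste(rownames(m), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(file)
}

#' @rdname write_triplet
#' @export
read_triplet <- function(file) {
  first <- readLines(file, n = 1)
  ids <- strsplit(sub("^#ids\t", "", first), "\t")[[1]]
  df <- utils::read.delim(file, skip = 1)
  n <- length(ids)
  m <- Matrix::sparseMatrix(i = df$i, j = df$j, x = df$value, dims = c(n, n),
                            dimnames = list(ids, ids), symmetric = TRUE)
  m
}

#' Export a network as an edge-list TSV or GraphML
#'
#' @param g an `igraph` graph with edge attribute `relation`.
#' @param file output path.
#' @param format `"tsv"` (source, target, relation) or `"graphml"`.
#' @export
write_network <- function(g, file, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, file, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    names(el)[1:2] <- c("source", "target")
    utils::write.table(el, file, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}
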