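#' Load the packaged trait-window gene table
#'
#' Returns the packaged transcription of the study's selected SNP windows
#' (per trait: chromosome, interval in Mb, percentage of additive genetic
#' variance, annotated gene symbols) in long form: one row per
#' (trait, window, member). The single lowercase miRNA symbol
#' ("bta-mir-2379") carries node type `miRNA`; all other members, including
#' uppercase MIR gene loci, are `gene`. A window with no annotated gene
#' keeps one row with `symbol = NA`.
#'
#' @return `data.frame` of class `"trait_window_table"` with columns `trait`,
#'   `chrom`, `start_mb`, `end_mb`, `gv_percent`, `symbol`, `node_type`.
#' @export
load_trait_windows <- function() {
  path <- system.file("extdata", "trait_windows.tsv", package = "wssgblup",
                      mustWork = TRUE)
  wide <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                            colClasses = c(chrom = "character"))
  rows <- lapply(seq_len(nrow(wide)), function(i) {
    genes <- strsplit(wide$genes[i], ";", fixed = TRUE)[[1]]
    if (identical(genes, "NOT_FOUND")) genes <- NA_character_
    data.frame(trait = wide$trait[i], chrom = wide$chrom[i],
               start_mb = wide$start_mb[i], end_mb = wide$end_mb[i],
               gv_percent = wide$gv_percent[i], symbol = genes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$node_type <- ifelse(is.na(out$symbol), NA_character_,
                          ifelse(out$symbol == tolower(out$symbol) &
                                   grepl("mir", out$symbol), "miRNA", "gene"))
  class(out) <- c("trait_window_table", "data.frame")
  out
}

#' Load the packaged miRNA-target fixture
#'
#' The suppressed-gene list of the reconstructed trait networks: per-trait
#' miRNA-to-gene attributions plus the globally suppressed genes that were
#' never attributed to a named miRNA (trait `ALL`, empty `mirna`).
#'
#' @return `data.frame` with columns `trait`, `mirna`, `gene`, `note`
#'   (`"not_in_table2"` flags a suppressed gene absent from every window).
#' @export
load_mirna_targets <- function() {
  path <- system.file("extdata", "mirna_targets.tsv", package = "wssgblup",
                      mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          fill = TRUE)
  for (cc in c("mirna", "note")) {
    df[[cc]][is.na(df[[cc]])] <- ""
  }
  df
}

#' Assign genes to selected windows by interval overlap
#'
#' A gene is assigned to a window when its interval overlaps the window's
#' closed interval on the same chromosome (`mode = "overlap"`, default) or
#' lies entirely inside it (`mode = "within"`).
#'
#' @param windows `data.frame` with columns `chrom`, `start_bp`, `end_bp`,
#'   `gv_percent` and optionally `trait` (filled with `"trait"` if absent),
#'   e.g. [select_windows] output.
#' @param genes `data.frame` with columns `symbol`, `chrom`, `start_bp`,
#'   `end_bp` (1-based inclusive) and optionally `node_type`.
#' @param mode `"overlap"` or `"within"`.
#' @return a `trait_window_table` (long form); windows without any assigned
#'   gene keep one row with `symbol = NA`.
#' @export
map_windows_to_genes <- function(windows, genes, mode = c("overlap", "within")) {
  mode <- match.arg(mode)
  if (is.null(windows$trait)) windows$trait <- "trait"
  if (is.null(genes$node_type)) genes$node_type <- "gene"
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    g <- genes[genes$chrom == w$chrom, , drop = FALSE]
    hit <- if (mode == "overlap")
      g$start_bp <= w$end_bp & g$end_bp >= w$start_bp
    else
      g$start_bp >= w$start_bp & g$end_bp <= w$end_bp
    data.frame(trait = w$trait, chrom = w$chrom, start_mb = w$start_bp / 1e6,
               end_mb = w$end_bp / 1e6, gv_percent = w$gv_percent,
               symbol = if (any(hit)) g$symbol[hit] else NA_character_,
               node_type = if (any(hit)) g$node_type[hit] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("trait_window_table", "data.frame")
  out
}

window_key <- function(table) {
  paste(table$chrom, table$start_mb, table$end_mb, sep = ":")
}

#' Summarise distinct, pleiotropic and trait-specific windows
#'
#' Windows are deduplicated by (chromosome, start, end); a window associated
#' with two or more traits is pleiotropic, otherwise trait-specific.
#'
#' @param table a `trait_window_table`.
#' @return list with `n_windows_distinct`, `n_pleiotropic`,
#'   `n_trait_specific` and the per-window trait lists (`windows`).
#' @export
pleiotropy_summary <- function(table) {
  key <- window_key(table)
  traits_by_window <- lapply(split(table$trait, key), unique)
  n_traits <- lengths(traits_by_window)
  list(n_windows_distinct = length(traits_by_window),
       n_pleiotropic = sum(n_traits >= 2),
       n_trait_specific = sum(n_traits == 1),
       windows = traits_by_window)
}

#' Count annotated genes per trait and overall
#'
#' Entry counts follow the convention of the source table: a symbol is
#' counted once per (trait, window) entry, so a gene sitting in two of a
#' trait's windows counts twice for that trait. `per_window_total` counts
#' entries over the distinct windows (each shared window counted once);
#' `unique_symbols` deduplicates symbols globally.
#'
#' @param table a `trait_window_table`.
#' @return list with `entries_by_trait`, `windows_by_trait`,
#'   `per_window_total`, `unique_symbols`.
#' @export
gene_counts <- function(table) {
  tab <- table[!is.na(table$symbol), , drop = FALSE]
  entries <- vapply(split(tab$symbol, tab$trait), length, integer(1))
  wins <- vapply(split(window_key(table), table$trait),
                 function(k) length(unique(k)), integer(1))
  key <- window_key(tab)
  per_window <- sum(vapply(split(tab$symbol, key),
                           function(s) length(unique(s)), integer(1)))
  list(entries_by_trait = entries, windows_by_trait = wins,
       per_window_total = per_window,
       unique_symbols = length(unique(tab$symbol)))
}

#' Genes shared between traits
#'
#' @param table a `trait_window_table`.
#' @param traits traits whose gene sets are intersected.
#' @param exclusive if TRUE, restrict to symbols annotated to no other trait.
#' @return character vector of symbols annotated to every trait in `traits`.
#' @export
trait_overlap <- function(table, traits, exclusive = FALSE) {
  known <- unique(table$trait)
  bad <- setdiff(traits, known)
  if (length(bad)) stop("unknown trait(s): ", paste(bad, collapse = ", "))
  tab <- table[!is.na(table$symbol), , drop = FALSE]
  sets <- lapply(split(tab$symbol, tab$trait), unique)
  common <- Reduce(intersect, sets[traits])
  if (exclusive && length(common)) {
    others <- unique(unlist(sets[setdiff(known, traits)]))
    common <- setdiff(common, others)
  }
  sort(common)
}

#' Bipartite trait-gene network
#'
#' One node per trait and per distinct member symbol; one `annotated_in`
#' edge per distinct (trait, symbol) pair.
#'
#' @param table a `trait_window_table`.
#' @return an `igraph` graph with vertex attribute `type` (`trait` / `gene` /
#'   `miRNA`) and edge attribute `relation`.
#' @export
build_gene_trait_network <- function(table) {
  tab <- table[!is.na(table$symbol), c("trait", "symbol", "node_type")]
  tab <- unique(tab)
  if (!nrow(tab))
    return(igraph::make_empty_graph(directed = FALSE))
  traits <- unique(tab$trait)
  symbols <- unique(tab[, c("symbol", "node_type")])
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = tab$trait, to = tab$symbol,
                   relation = "annotated_in"),
    directed = FALSE,
    vertices = data.frame(name = c(traits, symbols$symbol),
                          type = c(rep("trait", length(traits)),
                                   symbols$node_type)))
  g
}

#' Bipartite miRNA-gene network with optional gene-gene interactions
#'
#' @param targets `data.frame` with columns `mirna`, `gene` (rows with an
#'   empty or missing `mirna` are dropped).
#' @param interactions optional `data.frame` with columns `gene1`, `gene2`
#'   (protein-protein or pathway links); self-loops are rejected.
#' @return an `igraph` graph; vertex attribute `type` (`miRNA`/`gene`), edge
#'   attribute `relation` (`targets`/`interacts`). The attribute
#'   `hub` on the graph holds the maximum-degree gene node(s).
#' @export
build_mirna_gene_network <- function(targets, interactions = NULL) {
  targets <- targets[!is.na(targets$mirna) & targets$mirna != "", , drop = FALSE]
  edges <- data.frame(from = character(0), to = character(0),
                      relation = character(0), stringsAsFactors = FALSE)
  if (nrow(targets))
    edges <- unique(data.frame(from = targets$mirna, to = targets$gene,
                               relation = "targets", stringsAsFactors = FALSE))
  if (!is.null(interactions) && nrow(interactions)) {
    if (any(interactions$gene1 == interactions$gene2))
      stop("self-loops are not allowed in the interaction table")
    edges <- rbind(edges,
                   unique(data.frame(from = interactions$gene1,
                                     to = interactions$gene2,
                                     relation = "interacts",
                                     stringsAsFactors = FALSE)))
  }
  if (!nrow(edges)) return(igraph::make_empty_graph(directed = FALSE))
  mirnas <- unique(targets$mirna)
  genes <- setdiff(unique(c(edges$from, edges$to)), mirnas)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = c(mirnas, genes),
                          type = c(rep("miRNA", length(mirnas)),
                                   rep("gene", length(genes)))))
  deg <- igraph::degree(g)
  gene_deg <- deg[igraph::V(g)$type == "gene"]
  g$hub <- names(gene_deg)[gene_deg == max(gene_deg)]
  g
}

#' Hypergeometric over-representation test for gene sets
#'
#' For each named set, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap when `length(gene_list)` genes are sampled
#' from the background; Benjamini-Hochberg adjustment across sets.
#'
#' @param gene_list character vector of query genes (must be drawn from
#'   `background`).
#' @param background character vector, the annotation universe.
#' @param gene_sets named list of character vectors; members outside the
#'   background are ignored.
#' @return `data.frame` sorted by `p`: `term`, `overlap`, `term_size`,
#'   `list_size`, `background_size`, `p`, `p_adj`.
#' @export
hypergeometric_enrichment <- function(gene_list, background, gene_sets) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, background)
  if (length(outside))
    stop("gene list members outside the background: ",
         paste(utils::head(outside, 5), collapse = ", "))
  N <- length(background); k <- length(gene_list)
  res <- lapply(names(gene_sets), function(nm) {
    term <- intersect(unique(gene_sets[[nm]]), background)
    ov <- length(intersect(term, gene_list))
    p <- if (length(term) == 0 || ov == 0) {
      # P(X >= 0) = 1 covers the empty-term / no-overlap case
      if (ov == 0) 1 else NA_real_
    } else {
      stats::phyper(ov - 1, length(term), N - length(term), k,
                    lower.tail = FALSE)
    }
    data.frame(term = nm, overlap = ov, term_size = length(term),
               list_size = k, background_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
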