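#' Construct an expression matrix
#'
#' The shared expression container used throughout the package: a numeric
#' gene x sample matrix tagged with its unit (raw counts, TPM, or
#' log2(TPM + 1)) and, for count matrices, per-gene transcript lengths.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All values must be >= 0.
#' @param unit One of `"counts"`, `"tpm"`, `"log2tpm1"`.
#' @param gene_lengths Positive integer vector of summed exon lengths in
#'   bases, one per gene. Required when `unit = "counts"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, unit = c("counts", "tpm", "log2tpm1"),
                              gene_lengths = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id: ", rownames(values)[duplicated(rownames(values))][1])
  if (!is.numeric(values)) stop("values must be numeric")
  if (any(values < 0, na.rm = TRUE)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (unit == "counts") {
    if (is.null(gene_lengths))
      stop("gene_lengths are required when unit = 'counts'")
    if (length(gene_lengths) != nrow(values))
      stop("gene_lengths must have one entry per gene")
    if (any(gene_lengths <= 0)) stop("gene_lengths must be positive")
    names(gene_lengths) <- rownames(values)
  }
  structure(list(values = values, unit = unit, gene_lengths = gene_lengths),
            class = "ExpressionMatrix")
}

#' @exportS3Method base::print
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read a gene x sample count table from TSV
#'
#' First column holds gene ids; remaining columns are samples. An optional
#' `gene_length` column is taken as transcript length and removed from the
#' sample columns. Lines starting with '#' are comments.
#'
#' @param path Path to a tab-delimited file.
#' @param unit Unit to tag the result with (default `"counts"`).
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path, unit = "counts") {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected at least one sample column in ", path)
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1])
  df <- df[, -1, drop = FALSE]
  lengths <- NULL
  if ("gene_length" %in% colnames(df)) {
    lengths <- df[["gene_length"]]
    df <- df[, setdiff(colnames(df), "gene_length"), drop = FALSE]
  }
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                   gene_ids[bad], colnames(df)[j]))
    }
  }
  m <- as.matrix(df)
  rownames(m) <- gene_ids
  if (unit != "counts") lengths <- lengths  # lengths optional for tpm units
  expression_matrix(m, unit = unit,
                    gene_lengths = if (unit == "counts") lengths else lengths)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_counts()]: gene ids in the first column, a
#' `gene_length` column when lengths are attached, then one column per
#' sample.
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output path.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(m$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(m$gene_lengths)) df$gene_length <- m$gene_lengths
  df <- cbind(df, as.data.frame(m$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compute TPM from a count matrix
#'
#' Transcripts per million: per sample, each gene's count is divided by its
#' transcript length (summed exon length, in kilobases conceptually; any
#' consistent unit cancels), and the resulting rates are scaled to sum to
#' one million. Every sample column of the result sums to 1e6.
#'
#' @param m An `ExpressionMatrix` with `unit = "counts"` and gene lengths.
#' @return An `ExpressionMatrix` with `unit = "tpm"`.
#' @export
compute_tpm <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "counts") stop("compute_tpm expects unit = 'counts'")
  if (is.null(m$gene_lengths)) stop("gene_lengths required to compute TPM")
  rate <- m$values / m$gene_lengths
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(m$values)[tot == 0], collapse = ", "))
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  out <- expression_matrix(tpm, unit = "tpm")
  out$gene_lengths <- m$gene_lengths
  out
}

#' Log-transform a TPM matrix
#'
#' Elementwise log2(TPM + 1); the transform used to call a gene expressed
#' (mean transformed value >= 1 in a tissue).
#'
#' @param m An `ExpressionMatrix` with `unit = "tpm"`.
#' @return An `ExpressionMatrix` with `unit = "log2tpm1"`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "tpm") stop("log_transform expects unit = 'tpm'")
  out <- expression_matrix(log2(m$values + 1), unit = "log2tpm1")
  out$gene_lengths <- m$gene_lengths
  out
}

#' Read a sample table
#'
#' Tab-delimited with columns `sample_id`, `species` (one of `CF`, `PF`,
#' `F1`), `tissue` (brain, heart, liver, kidney, testis), and `cross`
#' (`CFfather_PFmother`, `PFfather_CFmother`, or `none`). Species are coded
#' collared flycatcher (CF) = 0 and pied flycatcher (PF) = 1 wherever a
#' numeric trait is needed.
#'
#' @param path Path to TSV.
#' @return A data.frame with validated columns and a numeric `species_code`
#'   (0 = CF, 1 = PF, NA = F1).
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' Validate a sample table built in code
#' @param df data.frame with sample_id, species, tissue, cross columns.
#' @return The validated data.frame with `species_code` attached.
#' @export
validate_sample_table <- function(df) {
  need <- c("sample_id", "species", "tissue", "cross")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("sample table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$species %in% c("CF", "PF", "F1")))
    stop("species must be CF, PF or F1")
  bad_cross <- df$species == "F1" & !(df$cross %in%
    c("CFfather_PFmother", "PFfather_CFmother"))
  if (any(bad_cross))
    stop("every F1 hybrid needs a cross direction: ",
         paste(df$sample_id[bad_cross], collapse = ", "))
  df$species_code <- c(CF = 0, PF = 1, F1 = NA)[df$species]
  df
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 is parsed with rtracklayer and assembled into one record per gene:
#' gene body interval, strand, ordered CDS exons with frame, and UTRs.
#' Coordinates are converted to 0-based half-open on read (GFF3 and BED
#' inputs are 1-based closed and 0-based half-open respectively); all
#' internal arithmetic, including flank windows, uses the half-open
#' convention.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param flank_bp Flank size in bases attached to each model (default 5000).
#' @return A list of gene model lists (fields `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `cds` data.frame, `utr5`, `utr3`, `flank_bp`).
#' @export
read_gene_models <- function(path, flank_bp = 5000) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    models <- lapply(seq_len(nrow(df)), function(i) {
      gene_model(gene_id = df[i, 4], chrom = df[i, 1],
                 start = df[i, 2], end = df[i, 3],
                 strand = df[i, 6], flank_bp = flank_bp)
    })
    names(models) <- vapply(models, `[[`, "", "gene_id")
    return(models)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", ]
  if (!nrow(genes)) stop("no gene features in ", path)
  gid <- function(x) if (!is.null(x$ID)) x$ID else x$Name
  models <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    id <- g$ID
    kids <- df[!is.na(df$Parent) & vapply(df$Parent, function(p) id %in% p, TRUE), ]
    # transcripts' children (CDS/UTR) point at the mRNA; accept either level
    tx_ids <- kids$ID[kids$type %in% c("mRNA", "transcript")]
    sub <- df[vapply(df$Parent, function(p) any(p %in% c(id, tx_ids)), TRUE), ]
    cds <- sub[sub$type == "CDS", c("start", "end", "phase")]
    cds$start <- cds$start - 1L  # to 0-based half-open
    cds <- cds[order(cds$start), ]
    if (as.character(g$strand) == "-") cds <- cds[rev(seq_len(nrow(cds))), ]
    u5 <- sub[sub$type %in% c("five_prime_UTR", "5UTR"), c("start", "end")]
    u3 <- sub[sub$type %in% c("three_prime_UTR", "3UTR"), c("start", "end")]
    u5$start <- u5$start - 1L; u3$start <- u3$start - 1L
    gene_model(gene_id = id, chrom = as.character(g$seqnames),
               start = g$start - 1L, end = g$end,
               strand = as.character(g$strand),
               cds = cds, utr5 = u5, utr3 = u3, flank_bp = flank_bp)
  })
  names(models) <- vapply(models, `[[`, "", "gene_id")
  models
}

#' Construct a gene model
#'
#' @param gene_id,chrom,start,end,strand Gene body interval (0-based
#'   half-open) and strand ("+" or "-").
#' @param cds data.frame with `start`, `end` (0-based half-open) and `phase`,
#'   ordered 5'->3' along the transcript. Total CDS length must be a multiple
#'   of 3 after the first exon's phase is trimmed.
#' @param utr5,utr3 data.frames with `start`, `end` intervals.
#' @param flank_bp Flank size in bases.
#' @return A list with class `GeneModel`.
#' @export
gene_model <- function(gene_id, chrom, start, end, strand,
                       cds = NULL, utr5 = NULL, utr3 = NULL, flank_bp = 5000) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (end <= start) stop("empty gene interval for ", gene_id)
  if (!is.null(cds) && nrow(cds)) {
    phase0 <- if ("phase" %in% colnames(cds) && !is.na(cds$phase[1]))
      as.integer(cds$phase[1]) else 0L
    len <- sum(cds$end - cds$start) - phase0
    if (len %% 3 != 0)
      stop("CDS length not divisible by 3 for ", gene_id)
  }
  structure(list(gene_id = gene_id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, cds = cds,
                 utr5 = utr5, utr3 = utr3, flank_bp = flank_bp),
            class = "GeneModel")
}

#' Read phased allele-specific counts for hybrids
#'
#' Expected columns: `hybrid_id`, `gene_id`, `snp_id`, optional `chrom`,
#' `pos`, then `maternal_reads`, `paternal_reads`. Counts must be
#' non-negative integers; phase (parent-of-origin) is assumed resolved
#' upstream.
#'
#' @param path Path to TSV.
#' @return data.frame of class `AlleleCountTable`.
#' @export
read_allele_counts <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("hybrid_id", "gene_id", "snp_id", "maternal_reads", "paternal_reads")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("allele count table missing: ",
                         paste(miss, collapse = ", "))
  if (any(df$maternal_reads < 0 | df$paternal_reads < 0))
    stop("negative read counts in ", path)
  class(df) <- c("AlleleCountTable", class(df))
  df
}

#' Read a protein-domain coordinate table
#'
#' Columns `protein_id`, `domain_id`, `start_aa`, `end_aa`; amino-acid
#' coordinates are 1-based inclusive.
#' @param path Path to TSV.
#' @return data.frame.
#' @export
read_domains <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "domain_id", "start_aa", "end_aa")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("domain table missing: ", paste(miss, collapse = ", "))
  if (any(df$end_aa < df$start_aa)) stop("domain end before start in ", path)
  df
}

#' Read a gene-set membership table
#'
#' Two-column TSV (`set_id`, `gene_id`), GO-style.
#' @param path Path to TSV.
#' @return Named list of character vectors, one per set.
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("gene set table needs set_id and gene_id columns")
  split(as.character(df[[2]]), df[[1]])
}

#' Read population genotypes and depths from VCF
#'
#' Parses VCF v4.x with vcfR and extracts per-sample genotypes (GT) and
#' read depths (DP). Only the fields this pipeline consumes are kept.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @return A list with `chrom`, `pos` (1-based, as in the file), `ref`,
#'   `alt`, `gt` (character matrix, sites x samples, e.g. "0/0"), and `dp`
#'   (integer matrix, NA where absent).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  fix <- vcfR::getFIX(v)
  list(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
       ref = fix[, "REF"], alt = fix[, "ALT"],
       gt = gt, dp = dp)
}

#' Read a rooted tree plus a one-site character over its tips
#'
#' @param tree_path newick file (read with ape); must be rooted.
#' @param states_path Either a 2-column TSV (`tip`, `state`) or a FASTA of
#'   single-character sequences named by tip.
#' @return A list with `tree` (phylo) and `tip_states` (named character
#'   vector over tips; NA for missing data).
#' @export
read_newick_with_characters <- function(tree_path, states_path) {
  tree <- ape::read.tree(tree_path)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (grepl("\\.(fa|fasta|faa)$", states_path, ignore.case = TRUE)) {
    ss <- Biostrings::readAAStringSet(states_path)
    states <- substr(as.character(ss), 1, 1)
    names(states) <- names(ss)
  } else {
    df <- utils::read.delim(states_path, comment.char = "#",
                            stringsAsFactors = FALSE)
    states <- as.character(df[[2]])
    names(states) <- df[[1]]
  }
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) stop("no state for tip(s): ", paste(miss, collapse = ", "))
  list(tree = tree, tip_states = states[tree$tip.label])
}

#' Write a results data.frame as TSV
#' @param df data.frame.
#' @param path Output path.
#' @param header_comments Optional character vector written as '#' lines.
#' @export
write_results_tsv <- function(df, path, header_comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comments))
    writeLines(paste0("# ", header_comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
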