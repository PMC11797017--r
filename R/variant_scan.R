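#' Coverage filter over VCF sites
#'
#' The strict reading keeps a site only when every individual has at least
#' `min_reads` reads there; the `"total"` mode keeps a site when the
#' summed depth over all individuals reaches `min_reads`.
#'
#' @param vcf List from [read_vcf_genotypes()] (or the simulator): needs a
#'   `dp` sites x individuals matrix.
#' @param min_reads Minimum depth (default 1).
#' @param mode `"each"` (strict, default) or `"total"`.
#' @return Logical vector over sites (TRUE = retained).
#' @export
coverage_filter <- function(vcf, min_reads = 1, mode = c("each", "total")) {
  mode <- match.arg(mode)
  dp <- vcf$dp
  if (is.null(dp)) stop("missing per-sample depth (DP) in VCF")
  if (anyNA(dp)) {
    bad <- which(rowSums(is.na(dp)) > 0)[1]
    stop("missing depth at site ", vcf$chrom[bad], ":", vcf$pos[bad])
  }
  if (mode == "each") apply(dp >= min_reads, 1, all)
  else rowSums(dp) >= min_reads
}

#' Fixed differences between two species from genotypes
#'
#' A biallelic site is a fixed difference when all covered individuals of
#' one species are homozygous for one allele and all covered individuals
#' of the other species are homozygous for the alternative allele.
#' Individuals with missing genotypes are excluded from the test; a site
#' needs at least one covered individual per species. Multiallelic sites
#' are skipped (counted).
#'
#' @param vcf List with `chrom`, `pos` (1-based), `ref`, `alt`, `gt`.
#' @param species_map Named character vector individual -> species (two
#'   species).
#' @param keep Optional logical site filter (e.g. from
#'   [coverage_filter()]).
#' @return data.frame of fixed-difference sites: `chrom`, `pos0` (0-based),
#'   `allele_A`, `allele_B` (first/second species level), with attribute
#'   `n_multiallelic_skipped`.
#' @export
fixed_differences <- function(vcf, species_map, keep = NULL) {
  sp <- sort(unique(species_map))
  if (length(sp) != 2) stop("species_map must contain exactly two species")
  inds <- colnames(vcf$gt)
  if (!all(inds %in% names(species_map)))
    stop("individuals missing from species_map")
  ia <- inds[species_map[inds] == sp[1]]
  ib <- inds[species_map[inds] == sp[2]]
  if (is.null(keep)) keep <- rep(TRUE, length(vcf$pos))
  n_multi <- 0L
  rows <- list()
  for (i in which(keep)) {
    if (grepl(",", vcf$alt[i])) { n_multi <- n_multi + 1L; next }
    g <- gsub("\\|", "/", vcf$gt[i, ])
    hom <- function(ids) {
      gg <- g[ids]
      gg <- gg[!is.na(gg) & gg != "./."]
      if (!length(gg)) return(NA_character_)
      if (all(gg == "0/0")) return(vcf$ref[i])
      if (all(gg == "1/1")) return(vcf$alt[i])
      NA_character_
    }
    aA <- hom(ia); aB <- hom(ib)
    if (!is.na(aA) && !is.na(aB) && aA != aB)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = vcf$chrom[i], pos0 = vcf$pos[i] - 1L,
        allele_A = aA, allele_B = aB, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos0 = integer(),
               allele_A = character(), allele_B = character())
  attr(out, "n_multiallelic_skipped") <- n_multi
  out
}

#' Assign a genomic site to gene regions
#'
#' Precedence: gene body (with 5'/3' UTR sublabels) over flanks over
#' intergenic. Flanks are strand-aware: `flank_up` is the 5' side of the
#' gene. All coordinates are 0-based half-open. A site overlapping several
#' genes yields one row per gene.
#'
#' @param pos0 0-based position.
#' @param gene_models List of gene models ([gene_model()]).
#' @param chrom Chromosome of the site.
#' @param flank_bp Flank size (default: each model's own `flank_bp`).
#' @return data.frame: `gene_id`, `region`; a single `intergenic` row when
#'   no gene is hit.
#' @export
assign_region <- function(pos0, gene_models, chrom = NULL, flank_bp = NULL) {
  hits <- list()
  for (gm in gene_models) {
    if (!is.null(chrom) && gm$chrom != chrom) next
    fb <- if (is.null(flank_bp)) gm$flank_bp else flank_bp
    inside <- function(iv) !is.null(iv) && nrow(iv) &&
      any(pos0 >= iv$start & pos0 < iv$end)
    region <- NULL
    if (pos0 >= gm$start && pos0 < gm$end) {
      region <- if (inside(gm$utr5)) "utr5"
        else if (inside(gm$utr3)) "utr3" else "gene_body"
    } else {
      left <- pos0 >= gm$start - fb && pos0 < gm$start
      right <- pos0 >= gm$end && pos0 < gm$end + fb
      if (left) region <- if (gm$strand == "+") "flank_up" else "flank_down"
      if (right) region <- if (gm$strand == "+") "flank_down" else "flank_up"
    }
    if (!is.null(region))
      hits[[length(hits) + 1]] <- data.frame(gene_id = gm$gene_id,
                                             region = region,
                                             stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(gene_id = NA_character_, region = "intergenic",
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

## ---- codon machinery -----------------------------------------------------

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                ""))
}

# genomic positions (0-based) of CDS bases in transcript (5'->3') order
cds_genomic_positions <- function(gm) {
  if (is.null(gm$cds) || !nrow(gm$cds)) stop("gene has no CDS: ", gm$gene_id)
  pos <- unlist(lapply(seq_len(nrow(gm$cds)), function(i)
    seq(gm$cds$start[i], gm$cds$end[i] - 1L)))
  if (gm$strand == "-") {
    # exons are stored transcript-ordered; within each exon reverse
    pos <- unlist(lapply(seq_len(nrow(gm$cds)), function(i)
      rev(seq(gm$cds$start[i], gm$cds$end[i] - 1L))))
  }
  pos
}

# transcript-sense codon for 1-based amino-acid position
codon_from_genome <- function(genome_seq, gm, aa_pos) {
  gpos <- cds_genomic_positions(gm)[(3 * aa_pos - 2):(3 * aa_pos)]
  bases <- substring(genome_seq, gpos + 1L, gpos + 1L)
  if (gm$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
  paste(bases, collapse = "")
}

translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[toupper(codon)]]
  if (is.null(aa)) stop("invalid codon: ", codon)
  aa
}

#' Translate a gene model's coding sequence
#' @param genome_seq Chromosome sequence (character scalar).
#' @param gm A gene model with CDS.
#' @return Amino-acid string.
#' @export
translate_gene <- function(genome_seq, gm) {
  gpos <- cds_genomic_positions(gm)
  bases <- substring(genome_seq, gpos + 1L, gpos + 1L)
  if (gm$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
  cds <- paste(bases, collapse = "")
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

#' Annotate the protein consequence of a coding SNP
#'
#' Builds the affected codon from the spliced CDS, respecting strand and
#' frame, substitutes the alternative allele, and translates both codons
#' with the standard genetic code.
#'
#' @param pos0 0-based genomic position of the site.
#' @param ref,alt Reference and alternative alleles (genomic strand).
#' @param gm Gene model whose CDS covers the site.
#' @param genome_seq Chromosome sequence (character scalar).
#' @return list: `consequence` ("synonymous"/"nonsynonymous"), `aa_pos`
#'   (1-based), `ref_aa`, `alt_aa`, `ref_codon`, `alt_codon`.
#' @export
annotate_consequence <- function(pos0, ref, alt, gm, genome_seq) {
  gpos <- cds_genomic_positions(gm)
  ci <- match(pos0, gpos)   # transcript coordinate (1-based)
  if (is.na(ci)) stop("site not inside the CDS of ", gm$gene_id)
  genome_base <- substr(genome_seq, pos0 + 1L, pos0 + 1L)
  if (genome_base != ref)
    stop(sprintf("reference mismatch at %s:%d (genome %s, VCF ref %s)",
                 gm$chrom, pos0, genome_base, ref))
  aa_pos <- (ci - 1L) %/% 3L + 1L
  codon_pos <- (ci - 1L) %% 3L + 1L
  ref_codon <- codon_from_genome(genome_seq, gm, aa_pos)
  ref_tx <- if (gm$strand == "+") ref else chartr("ACGT", "TGCA", ref)
  alt_tx <- if (gm$strand == "+") alt else chartr("ACGT", "TGCA", alt)
  stopifnot(substr(ref_codon, codon_pos, codon_pos) == ref_tx)
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- alt_tx
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  list(consequence = if (ref_aa == alt_aa) "synonymous" else "nonsynonymous",
       aa_pos = aa_pos, ref_aa = ref_aa, alt_aa = alt_aa,
       ref_codon = ref_codon, alt_codon = alt_codon)
}

#' Locate an amino-acid position relative to protein domains
#'
#' For each domain of the protein: `inside` when the substitution falls
#' within the 1-based inclusive domain interval, `within_10_of_start`
#' when it lies outside but no more than 10 residues from the domain's
#' first position, else `outside`.
#'
#' @param aa_pos 1-based amino-acid position.
#' @param domains data.frame with `protein_id`, `domain_id`, `start_aa`,
#'   `end_aa`; pass the rows for one protein.
#' @return data.frame: `domain_id`, `relation`, `distance_to_start`.
#' @export
domain_overlap <- function(aa_pos, domains) {
  if (!nrow(domains)) return(data.frame(domain_id = character(),
                                        relation = character(),
                                        distance_to_start = integer()))
  rel <- ifelse(aa_pos >= domains$start_aa & aa_pos <= domains$end_aa,
                "inside",
         ifelse(abs(aa_pos - domains$start_aa) <= 10,
                "within_10_of_start", "outside"))
  data.frame(domain_id = domains$domain_id, relation = rel,
             distance_to_start = abs(aa_pos - domains$start_aa),
             stringsAsFactors = FALSE)
}

#' Scan a population VCF for annotated fixed differences
#'
#' Runs the full variant stage: coverage filter, fixed-difference
#' detection, region assignment over the gene models (gene body, UTRs,
#' strand-aware +/- flank windows), codon-level consequence annotation for
#' CDS sites, and protein-domain overlap for nonsynonymous changes.
#'
#' @param vcf List from [read_vcf_genotypes()].
#' @param species_map Named individual -> species vector.
#' @param gene_models List of gene models.
#' @param genome Named character vector chromosome -> sequence.
#' @param domains Domain table ([read_domains()]), or NULL.
#' @param min_reads,coverage_mode Passed to [coverage_filter()].
#' @return data.frame, one row per fixed difference x overlapping gene:
#'   position, alleles, region, consequence, amino-acid change and domain
#'   relation (NA where not applicable).
#' @export
scan_fixed_differences <- function(vcf, species_map, gene_models, genome,
                                   domains = NULL, min_reads = 1,
                                   coverage_mode = "each") {
  keep <- coverage_filter(vcf, min_reads, coverage_mode)
  fd <- fixed_differences(vcf, species_map, keep)
  rows <- list()
  for (i in seq_len(nrow(fd))) {
    reg <- assign_region(fd$pos0[i], gene_models, chrom = fd$chrom[i])
    for (j in seq_len(nrow(reg))) {
      ann <- list(consequence = "noncoding", aa_pos = NA, ref_aa = NA,
                  alt_aa = NA)
      dom_rel <- NA_character_; dom_id <- NA_character_
      if (!is.na(reg$gene_id[j])) {
        gm <- gene_models[[reg$gene_id[j]]]
        in_cds <- !is.null(gm$cds) && nrow(gm$cds) &&
          any(fd$pos0[i] >= gm$cds$start & fd$pos0[i] < gm$cds$end)
        if (in_cds) {
          # orient so that the genome (assembly) allele is the reference
          gbase <- substr(genome[[gm$chrom]], fd$pos0[i] + 1L, fd$pos0[i] + 1L)
          al <- c(fd$allele_A[i], fd$allele_B[i])
          if (gbase == al[2]) al <- rev(al)
          ann <- annotate_consequence(fd$pos0[i], al[1], al[2], gm,
                                      genome[[gm$chrom]])
          if (al[1] != fd$allele_A[i]) {  # report change as species A -> B
            tmp <- ann$ref_aa; ann$ref_aa <- ann$alt_aa; ann$alt_aa <- tmp
          }
          if (ann$consequence == "nonsynonymous" && !is.null(domains)) {
            dd <- domains[domains$protein_id == gm$gene_id, , drop = FALSE]
            if (nrow(dd)) {
              ov <- domain_overlap(ann$aa_pos, dd)
              best <- order(match(ov$relation,
                                  c("inside", "within_10_of_start", "outside")))[1]
              dom_rel <- ov$relation[best]; dom_id <- ov$domain_id[best]
            }
          }
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        chrom = fd$chrom[i], pos0 = fd$pos0[i],
        allele_A = fd$allele_A[i], allele_B = fd$allele_B[i],
        gene_id = reg$gene_id[j], region = reg$region[j],
        consequence = ann$consequence, aa_pos = ann$aa_pos,
        aa_change = if (!is.na(ann$aa_pos))
          paste0(ann$ref_aa, "->", ann$alt_aa) else NA_character_,
        domain_id = dom_id, domain_relation = dom_rel,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
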