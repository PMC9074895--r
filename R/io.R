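#' Write transcriptome sequences as FASTA
#'
#' Concatenates each gene's 5' UTR, CDS, and 3' UTR into one mRNA record
#' and writes them, alongside optional per-region FASTA files.
#'
#' @param transcriptome output of [make_transcriptome()].
#' @param path output FASTA path for the full mRNAs.
#' @return invisibly, the written path.
#' @export
write_transcriptome_fasta <- function(transcriptome, path) {
  s <- transcriptome$seqs
  mrna <- Biostrings::DNAStringSet(paste0(as.character(s$utr5),
                                          as.character(s$cds),
                                          as.character(s$utr3)))
  names(mrna) <- names(s$utr5)
  Biostrings::writeXStringSet(mrna, path)
  invisible(path)
}

#' Write transcriptome gene models as GTF
#'
#' One "chromosome" per gene (transcript-space coordinates); each 3'-end
#' isoform becomes a transcript with an exon row covering UTR5 + CDS + its
#' 3'-UTR portion and a CDS row covering the ORF.
#'
#' @param transcriptome output of [make_transcriptome()].
#' @param path output GTF path.
#' @return invisibly, the written path.
#' @export
write_transcriptome_gtf <- function(transcriptome, path) {
  g <- transcriptome$genes
  iso <- transcriptome$isoforms
  rows <- lapply(seq_len(nrow(iso)), function(i) {
    gi <- g[g$gene == iso$gene[i], ]
    tx_len <- gi$len_utr5 + gi$len_cds + iso$end_offset[i]
    tid <- sprintf("%s.%d", iso$gene[i],
                   sum(iso$gene[seq_len(i)] == iso$gene[i]))
    data.frame(seqnames = gi$gene,
               start = c(1, gi$len_utr5 + 1),
               end = c(tx_len, gi$len_utr5 + gi$len_cds),
               type = c("exon", "CDS"),
               gene_id = gi$gene, transcript_id = tid)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqnames,
                               IRanges::IRanges(df$start, df$end),
                               strand = "+", type = df$type,
                               gene_id = df$gene_id,
                               transcript_id = df$transcript_id,
                               phase = ifelse(df$type == "CDS", 0L, NA_integer_))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write and read intensity traces as (gzipped) long TSV
#'
#' Long format: one row per tag and cycle with the four raw channel
#' intensities (`tag_id`, `cycle`, `A`, `C`, `G`, `T`).
#'
#' @param traces list with `tag_id` and channel matrices (see
#'   [simulate_intensity_tags()]).
#' @param path output path; a `.gz` suffix triggers compression.
#' @return invisibly, the written path.
#' @export
write_traces_tsv <- function(traces, path) {
  n <- length(traces$tag_id); Tn <- ncol(traces$A)
  dt <- data.table::data.table(
    tag_id = rep(traces$tag_id, times = Tn),
    cycle = rep(seq_len(Tn), each = n),
    A = as.vector(traces$A), C = as.vector(traces$C),
    G = as.vector(traces$G), T = as.vector(traces$T))
  data.table::setorder(dt, tag_id, cycle)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_traces_tsv
#' @export
read_traces_tsv <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    dt <- data.table::fread(text = readLines(con), sep = "\t")
  } else {
    dt <- data.table::fread(path, sep = "\t")
  }
  data.table::setorder(dt, tag_id, cycle)
  ids <- unique(dt$tag_id)
  Tn <- max(dt$cycle)
  shape <- function(col) matrix(dt[[col]], nrow = length(ids), ncol = Tn,
                                byrow = TRUE)
  list(tag_id = ids, A = shape("A"), C = shape("C"), G = shape("G"),
       T = shape("T"))
}

#' Thin TSV helpers
#'
#' `write_tsv`/`read_tsv` wrap data.table's fast writer/reader with the
#' pipeline's conventions (tab separator, no row names).
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv` returns a data.frame.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Serialize GHMM parameters to and from JSON
#'
#' @param params a [ghmm_params()] object.
#' @param path JSON path.
#' @return `read_ghmm_json` returns a `ghmm_params` object.
#' @export
write_ghmm_json <- function(params, path) {
  jsonlite::write_json(list(pi = params$pi, A = params$A, mu = params$mu,
                            sigma2 = params$sigma2),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_ghmm_json
#' @export
read_ghmm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ghmm_params(pi = x$pi, A = as.matrix(x$A), mu = x$mu, sigma2 = x$sigma2)
}

#' Serialize a synthetic configuration to and from YAML
#'
#' @param config a [synth_config()].
#' @param path YAML path.
#' @return `read_synth_config` returns a `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  cfg <- unclass(config)
  p <- cfg$ghmm_truth
  cfg$ghmm_truth <- list(pi = p$pi, A = as.vector(p$A), n_states = p$n_states,
                         mu = p$mu, sigma2 = p$sigma2)
  cfg$standards <- as.list(cfg$standards)
  for (nm in c("te_effects", "repression_by_site", "mechanism_fractions")) {
    cfg[[nm]] <- as.list(cfg[[nm]])
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gt <- cfg$ghmm_truth
  cfg$ghmm_truth <- ghmm_params(pi = gt$pi,
                                A = matrix(gt$A, gt$n_states, gt$n_states),
                                mu = gt$mu, sigma2 = gt$sigma2)
  cfg$standards <- as.data.frame(cfg$standards)
  for (nm in c("te_effects", "repression_by_site", "mechanism_fractions")) {
    cfg[[nm]] <- unlist(cfg[[nm]])
  }
  args <- cfg[intersect(names(cfg), names(formals(synth_config)))]
  do.call(synth_config, args)
}
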