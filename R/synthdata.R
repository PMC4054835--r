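# Synthetic single-cell experiment generator. Emulates the structure the
# downstream analyses assume: two cell types with planted differentially
# expressed genes, cell-cycle phase effects, per-gene lognormal biological
# fluctuation, lognormal technical noise, logistic dropout driven by
# expression level / GC content / transcript length, exogenous spike-in
# transcripts at fixed copy numbers, pooled single-cell-sized samples carrying
# technical error only, and FASTQ reads with planted amplification-adaptor
# sequences. Every draw is keyed to a master seed so results are reproducible
# and extensible (adding samples never perturbs existing ones).

DEFAULT_SPIKES <- c(Lys = 1000, Dap = 100, Phe = 20, Thr = 5)
SUPPRESSION_PRIMER <- "GTATAGAATTCGCGGCCGCTCGCGAT"

#' Default generator settings
#'
#' @param n_genes Number of endogenous genes.
#' @param n_de Number of differentially expressed genes between the two cell
#'   types (split evenly between up- and down-regulation in the second type).
#' @param de_log2fc_range Range of |log2 fold change| magnitudes, drawn
#'   uniformly for DE genes.
#' @param baseline_mean,baseline_sd Normal parameters for per-gene baseline
#'   log10 mean expression.
#' @param sigma_bio_range Per-gene biological fluctuation SD (log10 scale)
#'   drawn uniformly from this range. Magnitudes are free parameters of the
#'   generator, not protocol estimates.
#' @param sigma_tech Technical noise SD on the log10 scale.
#' @param cycle_fraction Fraction of genes with cell-cycle phase effects.
#' @param cycle_sd SD of S / G2M phase log10 offsets for cycling genes.
#' @param dropout_intercept,dropout_slope_expression,dropout_slope_gc,dropout_slope_length
#'   Logistic dropout coefficients; with positive slopes, dropout probability
#'   rises with GC content and falls with expression level and transcript
#'   length. Set `dropout_intercept = -Inf` to disable dropout.
#' @param spike_copies Named vector of spike-in copy numbers per
#'   cell-equivalent.
#' @param adaptor_rate Fraction of simulated reads carrying the adaptor.
#' @return A list of generator settings for [make_truth()].
#' @export
synth_config <- function(n_genes = 2000L,
                         n_de = 200L,
                         de_log2fc_range = c(1, 4),
                         baseline_mean = 1.2,
                         baseline_sd = 0.6,
                         sigma_bio_range = c(0.1, 0.5),
                         sigma_tech = 0.15,
                         cycle_fraction = 0.1,
                         cycle_sd = 0.3,
                         dropout_intercept = -2,
                         dropout_slope_expression = 2,
                         dropout_slope_gc = 1,
                         dropout_slope_length = 0.5,
                         spike_copies = DEFAULT_SPIKES,
                         adaptor_rate = 0.05) {
  as.list(environment())
}

#' Generate the ground truth for a synthetic experiment
#'
#' Draws the per-gene generative parameters (baseline expression, DE labels
#' and fold changes, fluctuation SDs, transcript length and GC content,
#' cell-cycle effects) plus the technical-noise and dropout parameters, all
#' deterministically from `seed`. The returned object is the reference every
#' recovery test scores against.
#'
#' @param config Settings from [synth_config()].
#' @param seed Integer master seed.
#' @return An object of class `SyntheticTruth` with elements `gene_table`,
#'   `noise_params`, `spike_copies`, `adaptor_rate`, `seed`.
#' @export
make_truth <- function(config = synth_config(), seed = 1L) {
  cfg <- utils::modifyList(synth_config(), config)
  if (cfg$n_de > cfg$n_genes)
    stop("n_de: DE gene count exceeds gene count")
  if (cfg$sigma_tech < 0) stop("sigma_tech: SD must be >= 0")
  if (any(cfg$sigma_bio_range < 0)) stop("sigma_bio_range: SDs must be >= 0")
  if (cfg$adaptor_rate < 0 || cfg$adaptor_rate > 1)
    stop("adaptor_rate: must lie in [0, 1]")
  if (any(cfg$spike_copies < 0)) stop("spike_copies: must be >= 0")

  n <- cfg$n_genes
  gt <- with_seed(derive_seed(seed, "truth"), {
    id <- sprintf("gene%05d", seq_len(n))
    transcript_length <- pmax(200L, as.integer(round(stats::rlnorm(n, log(1800), 0.6))))
    gc_fraction <- stats::rbeta(n, 24, 26)
    baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
    sigma_bio <- stats::runif(n, cfg$sigma_bio_range[1], cfg$sigma_bio_range[2])
    log2fc <- numeric(n)
    de_idx <- sample.int(n, cfg$n_de)
    mag <- stats::runif(cfg$n_de, cfg$de_log2fc_range[1], cfg$de_log2fc_range[2])
    sign <- rep_len(c(1, -1), cfg$n_de)
    log2fc[de_idx] <- mag * sign
    cyc <- stats::runif(n) < cfg$cycle_fraction
    cycle_S <- ifelse(cyc, stats::rnorm(n, 0, cfg$cycle_sd), 0)
    cycle_G2M <- ifelse(cyc, stats::rnorm(n, 0, cfg$cycle_sd), 0)
    data.frame(id = id, transcript_length = transcript_length,
               gc_fraction = gc_fraction, baseline_log10_mean = baseline,
               de_flag = log2fc != 0, log2_fold_change = log2fc,
               sigma_bio = sigma_bio, cycle_G1 = 0,
               cycle_S = cycle_S, cycle_G2M = cycle_G2M,
               stringsAsFactors = FALSE)
  })
  structure(list(
    gene_table = gt,
    noise_params = list(sigma_tech = cfg$sigma_tech,
                        dropout_intercept = cfg$dropout_intercept,
                        dropout_slope_expression = cfg$dropout_slope_expression,
                        dropout_slope_gc = cfg$dropout_slope_gc,
                        dropout_slope_length = cfg$dropout_slope_length),
    spike_copies = cfg$spike_copies,
    adaptor_rate = cfg$adaptor_rate,
    seed = as.integer(seed)),
    class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth: %d genes (%d DE), %d spike-ins, seed %d\n",
              nrow(x$gene_table), sum(x$gene_table$de_flag),
              length(x$spike_copies), x$seed))
  invisible(x)
}

#' Sample-layout helper for [simulate_experiment()]
#'
#' @param cell_type,cycle_phase,sample_class,n,batch Vectors (recycled) giving
#'   one design row per group; `n` samples are generated per row.
#' @return A design data.frame.
#' @export
design_grid <- function(cell_type, cycle_phase = "G1",
                        sample_class = "single_cell", n = 12L,
                        batch = "batch1") {
  data.frame(cell_type = cell_type,
             cycle_phase = rep_len(cycle_phase, length(cell_type)),
             sample_class = rep_len(sample_class, length(cell_type)),
             n = rep_len(as.integer(n), length(cell_type)),
             batch = rep_len(batch, length(cell_type)),
             stringsAsFactors = FALSE)
}

# dropout probability: logistic in log10 expression, GC fraction and log10
# transcript length (kb); positive slopes push dropout up with GC and down
# with expression and length
dropout_prob <- function(expr, gc, len, np) {
  stats::plogis(np$dropout_intercept -
                  np$dropout_slope_expression * log10(expr + 1) +
                  np$dropout_slope_gc * gc -
                  np$dropout_slope_length * log10(len / 1000))
}

#' Simulate a single-cell expression experiment
#'
#' For a single cell, each gene's expected expression is
#' `10^(baseline + cell-type effect + cycle effect + N(0, sigma_bio))`; the
#' measurement multiplies in lognormal technical noise `10^N(0, sigma_tech)`
#' and is zeroed with a logistic dropout probability. Pooled-equivalent and
#' bulk-reference samples use the population-mean expected expression (the
#' lognormal mean over the biological fluctuation — no cell-to-cell
#' deviation) with technical noise only. Spike-in transcripts are appended at
#' their configured copy numbers with technical noise only and no dropout.
#'
#' @param truth A [make_truth()] object.
#' @param design A [design_grid()] data.frame.
#' @param seed Integer master seed; each sample's random stream is derived
#'   from `(seed, sample_id)`, so extending the design leaves existing
#'   samples untouched.
#' @param dropout Apply dropout to endogenous genes (default TRUE).
#' @return A list with `matrix` ([expression_matrix()], unit FPKM, spike rows
#'   appended) and `annotation` ([sample_annotation()]).
#' @export
simulate_experiment <- function(truth, design, seed = 1L, dropout = TRUE) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  if (nrow(design) == 0L) stop("design must be non-empty")
  bad_phase <- !design$cycle_phase %in% c("G1", "S", "G2M")
  if (any(bad_phase))
    stop("unknown cycle_phase in design: ", design$cycle_phase[which(bad_phase)[1L]])
  gt <- truth$gene_table
  np <- truth$noise_params
  ln10 <- log(10)

  cols <- list(); ann_rows <- list()
  for (r in seq_len(nrow(design))) {
    d <- design[r, ]
    if (!d$cell_type %in% c("ES", "PrE"))
      stop("unknown cell_type in design: ", d$cell_type)
    type_eff <- if (d$cell_type == "PrE") gt$log2_fold_change * log10(2) else 0
    cyc_eff <- gt[[paste0("cycle_", d$cycle_phase)]]
    mu <- gt$baseline_log10_mean + type_eff + cyc_eff
    for (k in seq_len(d$n)) {
      sid <- sprintf("%s_%s_%s_%s_%02d", d$cell_type, d$cycle_phase,
                     d$sample_class, d$batch, k)
      vals <- with_seed(derive_seed(seed, sid), {
        if (d$sample_class == "single_cell") {
          expected <- 10^(mu + stats::rnorm(nrow(gt), 0, gt$sigma_bio))
        } else {
          # lognormal population mean over the biological fluctuation
          expected <- 10^mu * exp(0.5 * (gt$sigma_bio * ln10)^2)
        }
        v <- expected * 10^stats::rnorm(nrow(gt), 0, np$sigma_tech)
        if (dropout && is.finite(np$dropout_intercept)) {
          p <- dropout_prob(expected, gt$gc_fraction, gt$transcript_length, np)
          v[stats::runif(nrow(gt)) < p] <- 0
        }
        spikes <- truth$spike_copies *
          10^stats::rnorm(length(truth$spike_copies), 0, np$sigma_tech)
        c(v, spikes)
      })
      cols[[sid]] <- vals
      ann_rows[[sid]] <- data.frame(sample_id = sid, cell_type = d$cell_type,
                                    cycle_phase = d$cycle_phase,
                                    sample_class = d$sample_class,
                                    batch = d$batch, stringsAsFactors = FALSE)
    }
  }
  spike_ids <- paste0("spike_", names(truth$spike_copies))
  vals <- do.call(cbind, cols)
  rownames(vals) <- c(gt$id, spike_ids)
  meta <- data.frame(
    transcript_length = c(gt$transcript_length,
                          rep(1000L, length(spike_ids))),
    gc_fraction = c(gt$gc_fraction, rep(0.5, length(spike_ids))),
    row.names = rownames(vals))
  ann <- do.call(rbind, ann_rows)
  list(matrix = expression_matrix(vals, unit = "FPKM", gene_meta = meta),
       annotation = sample_annotation(ann$sample_id, ann$cell_type,
                                      ann$cycle_phase, ann$sample_class,
                                      ann$batch))
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

reverse_complement <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Simulate reads with planted adaptor contamination
#'
#' Exactly `round(n_reads * adaptor_rate)` reads carry the adaptor (forward
#' or reverse-complement orientation, uniform position); the rest are uniform
#' random bases. An optional uniform per-base substitution error is applied
#' to every read. Qualities are fixed at Phred 30.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length in bases; must be >= `nchar(adaptor)`.
#' @param adaptor Adaptor sequence (default: the whole-transcript
#'   amplification suppression-PCR primer).
#' @param adaptor_rate Fraction of reads carrying the adaptor, in \[0, 1\].
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A `ReadSet` data.frame; attribute `planted` is the logical vector
#'   of reads that carry the adaptor.
#' @export
simulate_reads <- function(n_reads, read_length = 50L,
                           adaptor = SUPPRESSION_PRIMER,
                           adaptor_rate = 0.1, error_rate = 0, seed = 1L) {
  if (adaptor_rate < 0 || adaptor_rate > 1)
    stop("adaptor_rate must lie in [0, 1]")
  if (grepl("[^ACGTUMRWSYKVHDBN]", toupper(adaptor)))
    stop("adaptor contains non-IUPAC characters")
  alen <- nchar(adaptor)
  if (read_length < alen)
    stop("read_length must be >= adaptor length (", alen, ")")
  n_plant <- round(n_reads * adaptor_rate)
  with_seed(derive_seed(seed, "reads"), {
    planted <- logical(n_reads)
    planted[sample.int(n_reads, n_plant)] <- TRUE
    bases <- vapply(seq_len(n_reads), function(i) {
      b <- random_bases(read_length)
      if (planted[i]) {
        ins <- if (stats::runif(1) < 0.5) adaptor else reverse_complement(adaptor)
        pos <- sample.int(read_length - alen + 1L, 1L)
        substr(b, pos, pos + alen - 1L) <- ins
      }
      b
    }, character(1))
    if (error_rate > 0) {
      bases <- vapply(bases, function(b) {
        v <- strsplit(b, "")[[1]]
        hit <- stats::runif(length(v)) < error_rate
        v[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
        paste(v, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    reads <- data.frame(read_id = sprintf("read%06d", seq_len(n_reads)),
                        bases = bases,
                        qualities = strrep("?", read_length),
                        stringsAsFactors = FALSE)
    class(reads) <- c("ReadSet", "data.frame")
    attr(reads, "planted") <- planted
    reads
  })
}

#' Write a synthetic truth table to TSV
#' @param truth A [make_truth()] object.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth$gene_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
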