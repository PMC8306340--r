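#' Design for a synthetic qPCR experiment
#'
#' Describes genes (targets plus reference genes used in combination as
#' internal controls), sample groups, and the true fold changes of each
#' target in each group relative to the calibrator group. Reference genes
#' have fold change 1 everywhere; the calibrator group has fold change 1 for
#' all genes.
#'
#' @param genes data.frame with columns `gene`, `role` (`"target"` or
#'   `"reference"`), and optionally `base_cq` and `efficiency`.
#' @param groups Character vector of group names; the first is the
#'   calibrator unless `calibrator` says otherwise.
#' @param fold_changes data.frame with columns `gene`, `group`,
#'   `fold_change` for target genes in non-calibrator groups (omitted pairs
#'   default to 1).
#' @param n_samples Biological samples per group.
#' @param n_replicates Technical replicates per (sample, gene).
#' @param cq_noise_sd Gaussian noise on each replicate Cq, cycles.
#' @param loading_sd Lognormal sigma of the per-sample global loading factor
#'   (shared by all genes of a sample, so reference normalization removes
#'   it).
#' @param base_cq Default base Cq for genes without their own.
#' @param efficiency Default amplification efficiency E in (1, 2].
#' @param calibrator Calibrator group name.
#' @param seed Integer seed.
#' @return An object of class `qpcr_design`.
#' @export
qpcr_design <- function(genes, groups, fold_changes = NULL,
                        n_samples = 3, n_replicates = 3,
                        cq_noise_sd = 0, loading_sd = 0,
                        base_cq = 24, efficiency = 2,
                        calibrator = groups[1], seed = NULL) {
  stopifnot(is.data.frame(genes), all(c("gene", "role") %in% names(genes)),
            all(genes$role %in% c("target", "reference")),
            length(groups) >= 1, calibrator %in% groups,
            n_samples >= 1, n_replicates >= 1, cq_noise_sd >= 0,
            loading_sd >= 0)
  if (is.null(genes$base_cq)) genes$base_cq <- base_cq
  if (is.null(genes$efficiency)) genes$efficiency <- efficiency
  if (any(genes$efficiency <= 1 | genes$efficiency > 2))
    stop("efficiency must be in (1, 2]")
  fc <- expand.grid(gene = genes$gene, group = groups,
                    stringsAsFactors = FALSE)
  fc$fold_change <- 1
  if (!is.null(fold_changes)) {
    stopifnot(all(c("gene", "group", "fold_change") %in% names(fold_changes)))
    for (i in seq_len(nrow(fold_changes))) {
      j <- fc$gene == fold_changes$gene[i] & fc$group == fold_changes$group[i]
      fc$fold_change[j] <- fold_changes$fold_change[i]
    }
  }
  ref <- genes$gene[genes$role == "reference"]
  if (any(fc$fold_change[fc$gene %in% ref] != 1))
    stop("reference genes must have fold change 1 in every group")
  if (any(fc$fold_change[fc$group == calibrator] != 1))
    stop("the calibrator group must have fold change 1 for all genes")
  if (any(fc$fold_change <= 0)) stop("fold changes must be > 0")
  structure(list(genes = genes, groups = groups, fold_changes = fc,
                 n_samples = n_samples, n_replicates = n_replicates,
                 cq_noise_sd = cq_noise_sd, loading_sd = loading_sd,
                 calibrator = calibrator, seed = seed),
            class = "qpcr_design")
}

#' Simulate a Cq table from a design
#'
#' `Cq(gene, sample) = base_cq - log_E(fold_change * loading) + noise`; the
#' per-sample loading factor is shared across genes, so reference-gene
#' normalization recovers the designed fold changes exactly in expectation
#' (and exactly, with noise 0).
#'
#' @param design A [qpcr_design()].
#' @return A long-format data.frame (class `cq_table`) with columns
#'   `sample`, `group`, `gene`, `role`, `replicate`, `cq`.
#' @export
simulate_cq_table <- function(design) {
  stopifnot(inherits(design, "qpcr_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  rows <- list()
  for (g in design$groups) {
    for (s in seq_len(design$n_samples)) {
      sample_id <- sprintf("%s_s%d", g, s)
      loading <- if (design$loading_sd > 0)
        exp(stats::rnorm(1, 0, design$loading_sd)) else 1
      for (i in seq_len(nrow(design$genes))) {
        gene <- design$genes$gene[i]
        E <- design$genes$efficiency[i]
        fcv <- design$fold_changes$fold_change[
          design$fold_changes$gene == gene & design$fold_changes$group == g]
        cq0 <- design$genes$base_cq[i] - log(fcv * loading, base = E)
        cq <- cq0 + if (design$cq_noise_sd > 0)
          stats::rnorm(design$n_replicates, 0, design$cq_noise_sd) else
          rep(0, design$n_replicates)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sample_id, group = g, gene = gene,
          role = design$genes$role[i],
          replicate = seq_len(design$n_replicates), cq = cq,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cq_table", "data.frame")
  out
}

#' Efficiency-corrected relative quantity
#'
#' `RQ = E^(cq_calibrator - cq)`.
#'
#' @param cq Quantification cycle(s).
#' @param cq_calibrator Calibrator Cq for the same gene.
#' @param efficiency Amplification efficiency E in (1, 2].
#' @return Relative quantity (vectorized).
#' @export
relative_quantity <- function(cq, cq_calibrator, efficiency = 2) {
  if (any(efficiency <= 1 | efficiency > 2)) stop("efficiency must be in (1, 2]")
  efficiency^(cq_calibrator - cq)
}

#' Normalization factor from reference-gene relative quantities
#'
#' Geometric mean of a sample's reference-gene RQs.
#'
#' @param ref_rq Numeric vector of reference-gene RQs (length >= 1).
#' @return Normalization factor.
#' @export
normalization_factor <- function(ref_rq) {
  if (length(ref_rq) < 1L) stop("at least one reference RQ required")
  if (any(ref_rq <= 0)) stop("reference RQs must be > 0")
  exp(mean(log(ref_rq)))
}

#' Normalized relative quantities with standard errors
#'
#' Technical replicates are collapsed to their mean Cq (replicate SDs above
#' `replicate_sd_warn` cycles are reported with a warning). Per sample,
#' `NRQ(gene) = RQ(gene) / NF` with NF the geometric mean of the sample's
#' reference-gene RQs. Group means and standard errors are computed on the
#' log scale across biological samples and back-transformed by the delta
#' method; finally every gene is rescaled so the calibrator-group mean NRQ
#' is 1.
#'
#' @param table A `cq_table` (long format: `sample`, `group`, `gene`,
#'   `role`, `cq`; a `replicate` column is optional).
#' @param calibrator Calibrator group name.
#' @param efficiencies Named vector of per-gene efficiencies (default 2 for
#'   genes not named).
#' @param replicate_sd_warn Replicate-SD threshold (cycles) for warnings.
#' @return A list of class `nrq_result`: `per_sample` (sample-level NRQ),
#'   `per_group` (gene x group mean NRQ and SE), `calibrator`,
#'   `efficiencies`.
#' @export
nrq <- function(table, calibrator, efficiencies = NULL,
                replicate_sd_warn = 0.5) {
  stopifnot(is.data.frame(table),
            all(c("sample", "group", "gene", "role", "cq") %in% names(table)))
  if (!calibrator %in% table$group) stop("calibrator group not in table")
  genes <- unique(table$gene)
  eff <- stats::setNames(rep(2, length(genes)), genes)
  if (!is.null(efficiencies)) eff[names(efficiencies)] <- efficiencies
  if (any(eff <= 1 | eff > 2)) stop("efficiency must be in (1, 2]")

  agg <- stats::aggregate(cq ~ sample + group + gene + role, data = table,
                          FUN = mean)
  sds <- stats::aggregate(cq ~ sample + gene, data = table,
                          FUN = stats::sd)
  bad <- !is.na(sds$cq) & sds$cq > replicate_sd_warn
  if (any(bad))
    warning(sprintf("%d (sample, gene) pairs have replicate Cq SD > %.2f cycles",
                    sum(bad), replicate_sd_warn))

  ref_genes <- unique(agg$gene[agg$role == "reference"])
  if (length(ref_genes) < 1L) stop("no reference genes in table")

  # samples must carry every reference gene
  samples <- unique(agg$sample)
  keep <- vapply(samples, function(s)
    all(ref_genes %in% agg$gene[agg$sample == s]), logical(1))
  if (!all(keep)) {
    warning(sprintf("excluding %d sample(s) lacking reference genes",
                    sum(!keep)))
    agg <- agg[agg$sample %in% samples[keep], , drop = FALSE]
  }

  # gene-wise calibrator mean Cq as the RQ anchor (cancels in the final
  # rescaling; used only for numerical centering)
  anchor <- vapply(genes, function(g)
    mean(agg$cq[agg$gene == g & agg$group == calibrator]), numeric(1))
  agg$rq <- relative_quantity(agg$cq, anchor[agg$gene], eff[agg$gene])

  nf <- vapply(unique(agg$sample), function(s)
    normalization_factor(agg$rq[agg$sample == s & agg$role == "reference"]),
    numeric(1))
  agg$nrq <- agg$rq / nf[agg$sample]

  tg <- agg[agg$role == "target", , drop = FALSE]
  per_group <- do.call(rbind, lapply(split(tg, list(tg$gene, tg$group),
                                           drop = TRUE), function(d) {
    l <- log(d$nrq)
    n <- length(l)
    data.frame(gene = d$gene[1], group = d$group[1], n = n,
               mean_log = mean(l),
               se_log = if (n > 1) stats::sd(l) / sqrt(n) else 0,
               stringsAsFactors = FALSE)
  }))
  # rescale so the calibrator group geometric-mean NRQ is 1 per gene
  cal <- per_group[per_group$group == calibrator, c("gene", "mean_log")]
  names(cal)[2] <- "cal_log"
  per_group <- merge(per_group, cal, by = "gene")
  per_group$nrq <- exp(per_group$mean_log - per_group$cal_log)
  per_group$se <- per_group$nrq * per_group$se_log
  per_group <- per_group[order(per_group$gene, per_group$group),
                         c("gene", "group", "n", "nrq", "se")]
  rownames(per_group) <- NULL

  tg <- merge(tg, cal, by = "gene")
  tg$nrq <- exp(log(tg$nrq) - tg$cal_log)
  per_sample <- tg[order(tg$gene, tg$group, tg$sample),
                   c("sample", "group", "gene", "nrq")]
  rownames(per_sample) <- NULL

  structure(list(per_sample = per_sample, per_group = per_group,
                 calibrator = calibrator, efficiencies = eff),
            class = "nrq_result")
}

#' Percent change between two normalized relative quantities
#'
#' `100 * (nrq_ref - nrq_a) / nrq_ref`; positive values are reductions
#' relative to the reference.
#'
#' @param nrq_a Quantity of interest.
#' @param nrq_ref Reference quantity (> 0).
#' @return Percent reduction (negative for increases).
#' @export
percent_change <- function(nrq_a, nrq_ref) {
  if (any(nrq_ref <= 0)) stop("reference NRQ must be > 0")
  100 * (nrq_ref - nrq_a) / nrq_ref
}
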