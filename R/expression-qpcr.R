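#' Ct table container
#'
#' A long-format qPCR cycle-threshold table with gene roles and the
#' reference group for relative quantification.
#'
#' @param data data.frame with columns `sample_id`, `group`, `gene`,
#'   `replicate`, `ct`.
#' @param gene_roles named character vector mapping each gene to `"target"`
#'   or `"housekeeping"`.
#' @param reference_group group label folds are expressed against.
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(data, gene_roles, reference_group) {
  need <- c("sample_id", "group", "gene", "replicate", "ct")
  if (!all(need %in% names(data)))
    stop_quant("ct data must have columns: %s", paste(need, collapse = ", "))
  genes <- unique(data$gene)
  missing_roles <- setdiff(genes, names(gene_roles))
  if (length(missing_roles))
    stop_quant("no role declared for gene(s): %s", paste(missing_roles, collapse = ", "))
  if (!all(gene_roles %in% c("target", "housekeeping")))
    stop_quant("gene roles must be 'target' or 'housekeeping'")
  if (!reference_group %in% data$group)
    stop_quant("reference_group '%s' absent from the table", reference_group)
  structure(list(data = data, gene_roles = gene_roles,
                 reference_group = reference_group),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  hk <- names(x$gene_roles)[x$gene_roles == "housekeeping"]
  cat(sprintf("<ct_table> %d rows, %d samples, genes: %s (housekeeping: %s), reference group: %s\n",
              nrow(x$data), length(unique(x$data$sample_id)),
              paste(unique(x$data$gene), collapse = ", "),
              paste(hk, collapse = ", "), x$reference_group))
  invisible(x)
}

#' Parameters for the synthetic qPCR generator
#'
#' Simulates a Ct table with known fold changes:
#' `Ct = baseline_ct[gene] + sample_shift - log2(fold_change[gene, group]) + noise`,
#' where the per-sample shift emulates loading/RT-efficiency differences
#' shared by all genes of a sample (removed exactly by housekeeping
#' normalisation) and the replicate noise emulates well-to-well variation.
#' Housekeeping genes have fold 1 in every group by constraint.
#'
#' @param genes character vector of gene names.
#' @param housekeeping exactly two housekeeping gene names (present in
#'   `genes`); defaults to the RNA assay pair ACTB/PABPN1.
#' @param groups group labels; the first is the reference group.
#' @param n_animals_per_group animals per group.
#' @param n_replicates technical replicates per sample x gene (assay
#'   convention: triplicate).
#' @param baseline_ct named numeric vector of reference-group Ct per gene
#'   (genes missing from it default to 22).
#' @param fold_change named list `gene -> named numeric (group -> fold)`;
#'   omitted entries default to 1. Housekeeping genes must be 1 (enforced).
#' @param ct_noise_sd replicate noise SD, Ct units.
#' @param sample_shift_sd per-sample global Ct shift SD.
#' @param seed integer seed.
#' @return A validated list of class `qpcr_sim_params`.
#' @export
qpcr_sim_params <- function(genes = c("Pgc1a", "Actb", "Pabpn1"),
                            housekeeping = c("Actb", "Pabpn1"),
                            groups = c("IRI+Veh", "IRI+NR"),
                            n_animals_per_group = 6,
                            n_replicates = 3,
                            baseline_ct = NULL,
                            fold_change = NULL,
                            ct_noise_sd = 0.2,
                            sample_shift_sd = 0.5,
                            seed = 1L) {
  if (length(housekeeping) != 2 || !all(housekeeping %in% genes))
    stop_quant("exactly two housekeeping genes, both present in 'genes', are required")
  if (n_replicates < 1) stop_quant("n_replicates must be >= 1")
  if (n_animals_per_group < 1) stop_quant("n_animals_per_group must be >= 1")
  check_positive(ct_noise_sd, "ct_noise_sd", strict = FALSE)
  check_positive(sample_shift_sd, "sample_shift_sd", strict = FALSE)
  bc <- stats::setNames(rep(22, length(genes)), genes)
  bc[intersect(housekeeping, genes)] <- 18
  if (!is.null(baseline_ct)) bc[names(baseline_ct)] <- baseline_ct
  fc <- matrix(1, length(genes), length(groups),
               dimnames = list(genes, groups))
  if (!is.null(fold_change)) {
    for (g in names(fold_change)) {
      v <- unlist(fold_change[[g]])  # accepts named vector or named list
      fc[g, names(v)] <- v
    }
  }
  if (any(fc[housekeeping, ] != 1))
    stop_quant("housekeeping genes must have fold change 1 in every group")
  if (any(fc[, groups[1]] != 1))
    stop_quant("fold changes in the reference group (first of 'groups') must be 1")
  if (any(fc <= 0)) stop_quant("fold changes must be > 0")
  structure(list(genes = genes, housekeeping = housekeeping, groups = groups,
                 n_animals_per_group = n_animals_per_group,
                 n_replicates = n_replicates, baseline_ct = bc,
                 fold_change = fc, ct_noise_sd = ct_noise_sd,
                 sample_shift_sd = sample_shift_sd, seed = seed),
            class = "qpcr_sim_params")
}

#' Generate a synthetic Ct table with known fold changes
#'
#' @param params a [qpcr_sim_params()] object.
#' @return A list with `table` (a [ct_table()]) and `truth` (class
#'   `ground_truth`: the gene x group matrix of true fold changes).
#' @export
generate_ct_table <- function(params) {
  stopifnot(inherits(params, "qpcr_sim_params"))
  p <- params
  with_seed(p$seed, {
    rows <- list()
    for (gi in seq_along(p$groups)) {
      grp <- p$groups[gi]
      for (a in seq_len(p$n_animals_per_group)) {
        sid <- sprintf("%s_a%02d", gsub("[^A-Za-z0-9]+", "", grp), a)
        shift <- stats::rnorm(1, sd = p$sample_shift_sd)
        for (g in p$genes) {
          true_ct <- p$baseline_ct[[g]] + shift - log2(p$fold_change[g, grp])
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, group = grp, gene = g,
            replicate = seq_len(p$n_replicates),
            ct = true_ct + stats::rnorm(p$n_replicates, sd = p$ct_noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    df <- do.call(rbind, rows)
    roles <- stats::setNames(
      ifelse(p$genes %in% p$housekeeping, "housekeeping", "target"), p$genes)
    truth <- structure(list(true_fold_changes = p$fold_change),
                       class = "ground_truth")
    list(table = ct_table(df, roles, reference_group = p$groups[1]),
         truth = truth)
  })
}

#' Average technical replicates
#'
#' Collapses a Ct table to one row per sample x gene with the arithmetic
#' mean Ct; the replicate count is retained in `n_replicates`.
#'
#' @param table a [ct_table()].
#' @return A [ct_table()] with averaged rows (replicate column = 1).
#' @export
average_replicates <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  d <- table$data
  key <- interaction(d$sample_id, d$gene, drop = TRUE)
  avg <- do.call(rbind, lapply(split(d, key), function(x) {
    data.frame(sample_id = x$sample_id[1], group = x$group[1],
               gene = x$gene[1], replicate = 1L,
               ct = mean(x$ct), n_replicates = nrow(x),
               stringsAsFactors = FALSE)
  }))
  rownames(avg) <- NULL
  avg <- avg[order(avg$sample_id, avg$gene), , drop = FALSE]
  ct_table(avg, table$gene_roles, table$reference_group)
}

#' Relative expression by the 2^-ddCt method
#'
#' Dual-housekeeping relative quantification. Technical replicates are
#' averaged first if needed. For each sample,
#' `dCt(gene) = Ct(gene) - mean(Ct(HK1), Ct(HK2))` — the arithmetic mean of
#' housekeeping Cts is exactly the geometric mean of the housekeeping
#' linear quantities on the Ct scale. Then
#' `ddCt = dCt - mean(dCt over reference-group samples)` and
#' `fold = 2^-ddCt`, so the reference group's fold changes have geometric
#' mean 1 by construction. Samples missing a housekeeping Ct are excluded,
#' with the reason recorded in the `"excluded"` attribute.
#'
#' @param table a [ct_table()] with exactly two housekeeping genes.
#' @return data.frame with `sample_id`, `group`, `gene`, `dct`, `ddct`,
#'   `fold` for every target gene, plus an `"excluded"` attribute.
#' @export
relative_expression <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  hk <- names(table$gene_roles)[table$gene_roles == "housekeeping"]
  if (length(hk) != 2)
    stop_quant("exactly 2 housekeeping genes required, found %d (%s)",
               length(hk), paste(hk, collapse = ", "))
  d <- table$data
  if (anyDuplicated(paste(d$sample_id, d$gene)))
    d <- average_replicates(table)$data
  targets <- names(table$gene_roles)[table$gene_roles == "target"]
  samples <- unique(d[, c("sample_id", "group")])
  excluded <- character(0)
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    ds <- d[d$sample_id == sid, , drop = FALSE]
    hk_ct <- ds$ct[match(hk, ds$gene)]
    if (anyNA(hk_ct)) {
      excluded <- c(excluded, sprintf(
        "%s: missing housekeeping Ct (%s)", sid,
        paste(hk[is.na(hk_ct)], collapse = ", ")))
      next
    }
    hk_mean <- mean(hk_ct)
    for (g in targets) {
      ctg <- ds$ct[match(g, ds$gene)]
      if (is.na(ctg)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, group = samples$group[i], gene = g,
        dct = ctg - hk_mean, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0) stop_quant("no usable samples")
  out <- list()
  for (g in targets) {
    dg <- res[res$gene == g, , drop = FALSE]
    ref <- dg$dct[dg$group == table$reference_group]
    if (length(ref) == 0)
      stop_quant("no reference-group samples for gene %s", g)
    dg$ddct <- dg$dct - mean(ref)
    dg$fold <- 2^(-dg$ddct)
    out[[g]] <- dg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Mitochondrial DNA copy ratio
#'
#' Relative mitochondrial DNA copy number (e.g. Mt-ND1, Mt-COX1) normalised
#' to the geometric mean of two nuclear-encoded single-copy genes
#' (NDUFV1, UBC) by the same 2^-ddCt machinery as [relative_expression()].
#'
#' @param table a [ct_table()] whose housekeeping pair are the nuclear
#'   reference genes of the DNA assay.
#' @return As [relative_expression()].
#' @export
mito_dna_ratio <- function(table) {
  relative_expression(table)
}

#' Per-group summary of fold changes
#'
#' Geometric mean (the natural average of folds) and n per group x gene.
#'
#' @param folds output of [relative_expression()].
#' @return data.frame `group`, `gene`, `geo_mean_fold`, `n`.
#' @export
group_fold_summary <- function(folds) {
  key <- interaction(folds$group, folds$gene, drop = TRUE)
  out <- do.call(rbind, lapply(split(folds, key), function(x) {
    data.frame(group = x$group[1], gene = x$gene[1],
               geo_mean_fold = exp(mean(log(x$fold))), n = nrow(x),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene, out$group), , drop = FALSE]
}
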