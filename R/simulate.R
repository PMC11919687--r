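#' Simulation configuration for synthetic multi-patient cohorts
#'
#' Defaults emulate a TIL-biopsy cohort of the kind used to train and audit a
#' tumor-reactivity predictor: 10 patients, 40 annotated clonotypes each,
#' small clones (geometric cell counts, mean 3), ~48% tumor-reactive clones,
#' negative-binomial UMI counts with log-normal gene baselines, and a planted
#' up/down expression program separating reactive from bystander cells.
#'
#' @param n_patients number of patients.
#' @param clones_per_patient annotated clonotypes per patient.
#' @param cells_per_clone_mean mean of the geometric (shifted by 1) cell
#'   count per clone.
#' @param n_genes number of genes.
#' @param n_signal_genes_up,n_signal_genes_down genes upregulated in reactive
#'   cells / upregulated in bystander cells (the down side of the reactive
#'   signature).
#' @param effect_size log-scale mean shift applied to signal genes
#'   (1 is a moderate ~e-fold shift; >=2 is strong).
#' @param nb_dispersion negative-binomial dispersion phi (Var = mu + phi mu^2).
#' @param frac_reactive fraction of clones labeled tumor-reactive, strictly
#'   inside (0, 1).
#' @param cdr3_cluster_count number of CDR3 sequence families planted in the
#'   cohort's beta chains.
#' @param cdr3_mutations_per_member substitutions separating a family member
#'   from its ancestor.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of gene
#'   baseline means.
#' @param seed integer seed; every simulation draw derives from it.
#' @return a list of class `SimConfig`.
#' @export
sim_config <- function(n_patients = 10, clones_per_patient = 40,
                       cells_per_clone_mean = 3, n_genes = 1000,
                       n_signal_genes_up = 30, n_signal_genes_down = 30,
                       effect_size = 1, nb_dispersion = 0.3,
                       frac_reactive = 0.48, cdr3_cluster_count = 8,
                       cdr3_mutations_per_member = 2,
                       baseline_meanlog = log(0.3), baseline_sdlog = 1.2,
                       seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_patients >= 1, clones_per_patient >= 1, n_genes >= 1,
              cells_per_clone_mean >= 1, n_signal_genes_up >= 0,
              n_signal_genes_down >= 0, nb_dispersion > 0,
              cdr3_cluster_count >= 1, cdr3_mutations_per_member >= 0)
    if (frac_reactive <= 0 || frac_reactive >= 1)
      stop("frac_reactive must be strictly inside (0, 1)")
    if (n_signal_genes_up + n_signal_genes_down > n_genes)
      stop("more signal genes than genes")
  })
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a multi-patient cohort with planted tumor-reactivity structure
#'
#' Counts are negative-binomial with gene-specific log-normal baseline means.
#' In cells of tumor-reactive clones the up-signal genes have their mean
#' multiplied by `exp(effect_size)`; in bystander cells the down-signal genes
#' are shifted up by the same factor (so they are downregulated in reactive
#' cells). Labels are assigned at clone level and broadcast to cells. CDR3
#' beta chains carry a planted family structure; a deterministic
#' physicochemical rule on the beta chain defines ground-truth structural
#' avidity, so the avidity classifier has something to recover.
#'
#' @param cfg a [sim_config()].
#' @return list with `cm` (a normalized [CellMatrix()]), `ct` (a
#'   [CloneTable()] with labels, frequencies and ground-truth
#'   `avidity_truth`), and `truth` (signal gene ids and CDR3 family labels).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  n_clones <- cfg$n_patients * cfg$clones_per_patient
  n_reactive_pp <- round(cfg$frac_reactive * cfg$clones_per_patient)
  if (n_reactive_pp < 1 || n_reactive_pp >= cfg$clones_per_patient)
    stop("degenerate config: frac_reactive rounds to 0 or all reactive clones")

  clone_patient <- rep(patients, each = cfg$clones_per_patient)
  clone_id <- sprintf("%s_C%03d", clone_patient,
                      unlist(lapply(patients, function(p) seq_len(cfg$clones_per_patient))))
  reactive <- unlist(lapply(patients, function(p) {
    lab <- rep(FALSE, cfg$clones_per_patient)
    lab[sample.int(cfg$clones_per_patient, n_reactive_pp)] <- TRUE
    lab
  }))

  n_cells_clone <- stats::rgeom(n_clones, prob = 1 / cfg$cells_per_clone_mean) + 1L
  cell_clone <- rep(seq_len(n_clones), n_cells_clone)
  n_cells <- length(cell_clone)
  barcodes <- sprintf("%s_BC%05d", clone_patient[cell_clone], seq_len(n_cells))

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  up_idx <- seq_len(cfg$n_signal_genes_up)
  down_idx <- cfg$n_signal_genes_up + seq_len(cfg$n_signal_genes_down)
  base_mu <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)

  cell_reactive <- reactive[cell_clone]
  mu <- matrix(base_mu, nrow = cfg$n_genes, ncol = n_cells)
  if (length(up_idx))
    mu[up_idx, cell_reactive] <- mu[up_idx, cell_reactive] * exp(cfg$effect_size)
  if (length(down_idx))
    mu[down_idx, !cell_reactive] <- mu[down_idx, !cell_reactive] * exp(cfg$effect_size)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = cfg$n_genes,
                   dimnames = list(genes, barcodes))

  fams <- simulate_cdr3_families(cfg$cdr3_cluster_count,
                                 members_per_family = ceiling(n_clones / cfg$cdr3_cluster_count),
                                 mutations = cfg$cdr3_mutations_per_member,
                                 seed = cfg$seed + 1L)
  fams <- fams[seq_len(n_clones), ]
  cdr3b <- fams$cdr3
  cdr3a <- simulate_cdr3_families(cfg$cdr3_cluster_count,
                                  members_per_family = ceiling(n_clones / cfg$cdr3_cluster_count),
                                  mutations = cfg$cdr3_mutations_per_member,
                                  seed = cfg$seed + 2L)$cdr3[seq_len(n_clones)]
  # ground-truth avidity: first physicochemical factor of the central residues
  feat1 <- vapply(cdr3b, function(s) featurize_cdr3(s)[["f1"]], numeric(1))
  avidity_truth <- ifelse(feat1 > stats::median(feat1), "high", "low")

  cell_meta <- data.frame(barcode = barcodes,
                          patient = clone_patient[cell_clone],
                          clone_id = clone_id[cell_clone],
                          stringsAsFactors = FALSE)
  cm <- normalize_log(CellMatrix(counts, cell_meta))

  freq <- stats::ave(n_cells_clone, clone_patient,
                     FUN = function(v) v / sum(v))
  ct <- CloneTable(data.frame(
    clone_id = clone_id, patient = clone_patient,
    cdr3a = cdr3a, cdr3b = cdr3b, n_cells = n_cells_clone,
    label = ifelse(reactive, "tumor_reactive", "non_tumor_reactive"),
    frequency = freq, stringsAsFactors = FALSE))
  ct$avidity_truth <- avidity_truth

  list(cm = cm, ct = ct,
       truth = list(up_genes = genes[up_idx], down_genes = genes[down_idx],
                    cdr3b_family = fams$family[seq_len(n_clones)]))
}

#' Simulate CDR3 sequence families
#'
#' Each family derives from one random ancestor (length 10-18, canonical
#' 20-letter alphabet) by exactly `mutations` random substitutions per
#' member, so members stay within `mutations` substitutions of the ancestor.
#'
#' @param k number of families.
#' @param members_per_family members per family.
#' @param mutations substitutions per member.
#' @param seed integer seed.
#' @return data.frame with `cdr3` and `family`.
#' @export
simulate_cdr3_families <- function(k, members_per_family, mutations = 2,
                                   seed = 1L) {
  stopifnot(k >= 1, members_per_family >= 1, mutations >= 0)
  set.seed(seed)
  rows <- lapply(seq_len(k), function(f) {
    len <- sample(10:18, 1)
    anc <- sample(AA_ALPHABET, len, replace = TRUE)
    seqs <- vapply(seq_len(members_per_family), function(m) {
      s <- anc
      if (mutations > 0) {
        pos <- sample.int(len, min(mutations, len))
        s[pos] <- sample(AA_ALPHABET, length(pos), replace = TRUE)
      }
      paste(s, collapse = "")
    }, character(1))
    data.frame(cdr3 = seqs, family = f, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # interleave families so that truncation keeps all of them represented
  out[order(stats::ave(seq_len(nrow(out)), out$family, FUN = seq_along),
            out$family), , drop = FALSE]
}

#' Permute clone-level tumor-reactivity labels
#'
#' Used by y-randomization: the multiset of labels is preserved and the
#' assignment to clones is uniformly random under the seed.
#'
#' @param ct a [CloneTable()] with labels.
#' @param seed integer seed.
#' @return the CloneTable with permuted `label`.
#' @export
permute_labels <- function(ct, seed = NULL) {
  stopifnot(inherits(ct, "CloneTable"))
  if (!is.null(seed)) set.seed(seed)
  ct$label <- ct$label[sample.int(nrow(ct))]
  ct
}
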