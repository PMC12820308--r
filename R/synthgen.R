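# Synthetic EHR heterogeneous-graph generator with planted, tunable disease
# structure: class-conditional drug/procedure propensities, Poisson event
# counts (floored at 1 so no patient is edgeless before noise), and three
# noise channels emulating imperfect clinical records - spurious edges,
# dropped edges, and label noise (applied after edge generation, so features
# reflect the true class: diagnostic-label error, the harder regime).

#' Specification of a synthetic EHR graph
#'
#' Defaults describe the easy benchmark world used throughout the package's
#' tests: 600 patients over 3 disease classes with 90 drugs and 45 procedures,
#' ~8 drug and ~3 procedure events per patient, 90% of events drawn from the
#' class's preferred subset, and 5% spurious-edge/edge-dropout/label-noise
#' rates (sparsity then lands in the regime of real patient-drug-procedure
#' graphs, around 0.9-0.99).
#'
#' @param n_patients,n_drugs,n_procedures,n_classes node/class counts
#'   (`n_classes >= 2`, `n_patients >= n_classes`).
#' @param drugs_per_patient_mean,procedures_per_patient_mean Poisson means of
#'   per-patient event counts (floored at 1).
#' @param signal_strength probability in `[0, 1]` that an event is drawn from
#'   the patient's class-specific preferred subset rather than uniformly.
#' @param preferred_drugs,preferred_procedures preferred-subset sizes per
#'   class; default `floor(n / n_classes)` (subsets are then disjoint).
#' @param spurious_edge_rate fraction of extra random non-edges added.
#' @param edge_dropout_rate probability each true edge is dropped.
#' @param label_noise_rate probability a patient's observed label is flipped
#'   to a different class.
#' @param seed integer seed; generation is fully deterministic per seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_patients = 600L, n_drugs = 90L, n_procedures = 45L,
                       n_classes = 3L, drugs_per_patient_mean = 8,
                       procedures_per_patient_mean = 3, signal_strength = 0.9,
                       preferred_drugs = NULL, preferred_procedures = NULL,
                       spurious_edge_rate = 0.05, edge_dropout_rate = 0.05,
                       label_noise_rate = 0.05, seed = 1L) {
  stopifnot(n_classes >= 2, n_patients >= n_classes,
            signal_strength >= 0, signal_strength <= 1,
            spurious_edge_rate >= 0, spurious_edge_rate <= 1,
            edge_dropout_rate >= 0, edge_dropout_rate <= 1,
            label_noise_rate >= 0, label_noise_rate <= 1,
            drugs_per_patient_mean > 0, procedures_per_patient_mean > 0)
  if (is.null(preferred_drugs)) preferred_drugs <- max(1L, n_drugs %/% n_classes)
  if (is.null(preferred_procedures)) {
    preferred_procedures <- max(1L, n_procedures %/% n_classes)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_drugs = as.integer(n_drugs),
                 n_procedures = as.integer(n_procedures),
                 n_classes = as.integer(n_classes),
                 drugs_per_patient_mean = drugs_per_patient_mean,
                 procedures_per_patient_mean = procedures_per_patient_mean,
                 signal_strength = signal_strength,
                 preferred_drugs = as.integer(preferred_drugs),
                 preferred_procedures = as.integer(preferred_procedures),
                 spurious_edge_rate = spurious_edge_rate,
                 edge_dropout_rate = edge_dropout_rate,
                 label_noise_rate = label_noise_rate,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Disjoint-when-possible preferred subsets: consecutive blocks of a permuted
# item order; wraps around (overlapping) when items are scarce.
preferred_sets <- function(n_items, n_classes, size) {
  perm <- sample.int(n_items)
  lapply(seq_len(n_classes), function(cl) {
    pos <- ((cl - 1L) * size + seq_len(size) - 1L) %% n_items + 1L
    sort(perm[pos])
  })
}

draw_events <- function(n_events, preferred, n_items, signal) {
  from_pref <- stats::runif(n_events) < signal
  ev <- integer(n_events)
  if (any(from_pref)) {
    ev[from_pref] <- preferred[sample.int(length(preferred),
                                          sum(from_pref), replace = TRUE)]
  }
  if (any(!from_pref)) {
    ev[!from_pref] <- sample.int(n_items, sum(!from_pref), replace = TRUE)
  }
  unique(ev)
}

apply_edge_noise <- function(edges, n_patients, n_items, drop_rate, spur_rate) {
  if (nrow(edges) && drop_rate > 0) {
    edges <- edges[stats::runif(nrow(edges)) >= drop_rate, , drop = FALSE]
  }
  n_add <- round(spur_rate * nrow(edges))
  if (n_add > 0) {
    key <- function(p, it) (p - 1) * n_items + it
    have <- key(edges[, 1], edges[, 2])
    cand_p <- sample.int(n_patients, 4L * n_add, replace = TRUE)
    cand_i <- sample.int(n_items, 4L * n_add, replace = TRUE)
    keep <- !duplicated(key(cand_p, cand_i)) & !(key(cand_p, cand_i) %in% have)
    take <- which(keep)[seq_len(min(n_add, sum(keep)))]
    edges <- rbind(edges, cbind(cand_p[take], cand_i[take]))
  }
  edges
}

#' Generate a synthetic EHR heterogeneous graph
#'
#' Each patient receives one true class label uniformly at random; its drug
#' and procedure events are drawn from the class's preferred subset with
#' probability `signal_strength` and uniformly otherwise (Poisson counts,
#' floor 1). Spurious edges are then added uniformly over non-edges, true
#' edges are dropped, and observed labels are flipped at the stated rates.
#' Deterministic per seed.
#'
#' @param spec a [synth_spec()].
#' @return A list with `graph` (a [het_graph()]), `labels` (observed integer
#'   labels 1..C aligned with `graph$nodes$P`) and `truth` (a record holding
#'   the pre-noise labels, the preferred subsets, and the spec).
#' @export
simulate_ehr_graph <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  C <- spec$n_classes
  true_labels <- sample.int(C, spec$n_patients, replace = TRUE)
  pref_d <- preferred_sets(spec$n_drugs, C, spec$preferred_drugs)
  pref_o <- preferred_sets(spec$n_procedures, C, spec$preferred_procedures)

  pd <- po <- vector("list", spec$n_patients)
  for (p in seq_len(spec$n_patients)) {
    cl <- true_labels[p]
    nd <- max(1L, stats::rpois(1, spec$drugs_per_patient_mean))
    no <- max(1L, stats::rpois(1, spec$procedures_per_patient_mean))
    ds <- draw_events(nd, pref_d[[cl]], spec$n_drugs, spec$signal_strength)
    os <- draw_events(no, pref_o[[cl]], spec$n_procedures,
                      spec$signal_strength)
    pd[[p]] <- cbind(p, ds)
    po[[p]] <- cbind(p, os)
  }
  pd <- do.call(rbind, pd)
  po <- do.call(rbind, po)
  pd <- apply_edge_noise(pd, spec$n_patients, spec$n_drugs,
                         spec$edge_dropout_rate, spec$spurious_edge_rate)
  po <- apply_edge_noise(po, spec$n_patients, spec$n_procedures,
                         spec$edge_dropout_rate, spec$spurious_edge_rate)

  labels <- true_labels
  flip <- stats::runif(spec$n_patients) < spec$label_noise_rate
  if (any(flip) && C >= 2) {
    labels[flip] <- vapply(labels[flip], function(cl) {
      sample(setdiff(seq_len(C), cl), 1L)
    }, 0L)
  }

  wp <- nchar(as.character(spec$n_patients))
  wd <- nchar(as.character(spec$n_drugs))
  wo <- nchar(as.character(spec$n_procedures))
  pid <- sprintf(paste0("p%0", wp, "d"), seq_len(spec$n_patients))
  did <- sprintf(paste0("d%0", wd, "d"), seq_len(spec$n_drugs))
  oid <- sprintf(paste0("o%0", wo, "d"), seq_len(spec$n_procedures))
  graph <- het_graph(
    pd_edges = data.frame(src = pid[pd[, 1]], dst = did[pd[, 2]]),
    po_edges = data.frame(src = pid[po[, 1]], dst = oid[po[, 2]]),
    patients = pid, drugs = did, procedures = oid)
  list(graph = graph, labels = labels,
       truth = list(true_labels = true_labels, preferred_drugs = pref_d,
                    preferred_procedures = pref_o, spec = spec))
}
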