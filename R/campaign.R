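#' Run a microstroke campaign
#'
#' End-to-end experiment: baseline solve on a network, candidate selection
#' with per-criterion survivor counts, classification of all candidates,
#' and one microstroke per selected MSC (up to `per_type` per topological
#' configuration), returning the stroke results together with the
#' bookkeeping needed for the summaries. Deterministic given (network, bc,
#' seed).
#'
#' @param g an [mvn_graph()].
#' @param bc a [boundary_conditions()].
#' @param cfg a [stroke_config()].
#' @param per_type number of microstrokes per MSC type (candidates are
#'   sampled without replacement when more are eligible), default 20.
#' @param mode `"steady"` or `"rbc"`.
#' @param seed integer seed.
#' @param ... passed to [run_single_stroke()].
#' @return list of class `stroke_campaign`: `baseline`, `selection`,
#'   `types` (per-candidate type), `strokes` (list of `stroke_result`),
#'   `seed`.
#' @export
run_campaign <- function(g, bc, cfg = stroke_config(), per_type = 20,
                         mode = "steady", seed = 1L, ...) {
  baseline <- if (mode == "steady") solve_pressure_flow(g, bc)
  else run_and_average(g, bc, seed = seed, ...)
  sel <- select_msc_candidates(g, baseline, cfg)
  inc <- incidence_list(g)
  types <- vapply(sel$candidates, function(v)
    classify_msc_type(g, baseline, v, inc = inc) %||% NA_character_, character(1))
  keep <- !is.na(types)
  cand <- data.frame(vessel = sel$candidates[keep], type = types[keep],
                     stringsAsFactors = FALSE)
  chosen <- with_seed(seed, {
    do.call(rbind, lapply(split(cand, cand$type), function(d) {
      if (nrow(d) > per_type) d[sample.int(nrow(d), per_type), ] else d
    }))
  })
  strokes <- lapply(seq_len(nrow(chosen)), function(i) {
    run_single_stroke(g, bc, chosen$vessel[i], cfg, mode = mode,
                      baseline = baseline, seed = seed, ...)
  })
  structure(list(baseline = baseline, selection = sel, candidates = cand,
                 chosen = chosen, strokes = strokes, seed = seed,
                 mode = mode, config = cfg),
            class = "stroke_campaign")
}

#' Summarize a set of microstroke simulations
#'
#' Per-simulation, per-generation mean thresholded relative flow change
#' restricted to vessels with a flow decrease, aggregated into per-type,
#' per-generation medians with seeded bootstrap confidence intervals; the
#' per-generation frequency of flow decreases; and the MSC-type census
#' (frequency of occurrence and median baseline flow per type).
#'
#' @param strokes list of `stroke_result`s (or a `stroke_campaign`).
#' @param g the [mvn_graph()] the strokes were run on.
#' @param ci confidence level for the bootstrap, default 0.95.
#' @param n_boot bootstrap resamples, default 1e4.
#' @param seed bootstrap seed, default 1.
#' @return list with data.frames `per_generation` (type, generation,
#'   median_dq, ci_lo, ci_hi, n), `decrease_frequency`, and `type_census`.
#' @export
summarize_strokes <- function(strokes, g, ci = 0.95, n_boot = 1e4, seed = 1L) {
  if (inherits(strokes, "stroke_campaign")) strokes <- strokes$strokes
  if (!length(strokes)) stop("no stroke results to summarize")
  rows <- lapply(strokes, function(s) {
    gens <- s$generations
    if (!nrow(gens)) return(NULL)
    vi <- match(gens$vessel, g$vessels$id)
    qb <- abs(flow_of(s$baseline, g)[vi])
    qs <- abs(flow_of(s$stroke, g)[vi])
    dq <- s$dq[vi]
    dec <- qs < qb
    per_gen <- tapply(dq[dec], gens$generation[dec], mean)
    freq <- tapply(dec, gens$generation, mean)
    data.frame(msc = s$msc, type = s$msc_type %||% NA_character_,
               generation = as.integer(names(freq)),
               mean_dq = as.numeric(per_gen[names(freq)]),
               decrease_freq = as.numeric(freq))
  })
  per_sim <- do.call(rbind, rows)
  boot_median <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    meds <- vapply(seq_len(n_boot), function(i)
      stats::median(sample(x, replace = TRUE)), numeric(1))
    a <- (1 - ci) / 2
    c(stats::median(x), stats::quantile(meds, a, names = FALSE),
      stats::quantile(meds, 1 - a, names = FALSE))
  }
  per_generation <- with_seed(seed, {
    do.call(rbind, lapply(split(per_sim, list(per_sim$type, per_sim$generation),
                                drop = TRUE), function(d) {
      bm <- boot_median(d$mean_dq)
      data.frame(type = d$type[1], generation = d$generation[1],
                 median_dq = bm[1], ci_lo = bm[2], ci_hi = bm[3],
                 n = nrow(d))
    }))
  })
  decrease_frequency <- do.call(rbind, lapply(
    split(per_sim, list(per_sim$type, per_sim$generation), drop = TRUE),
    function(d) data.frame(type = d$type[1], generation = d$generation[1],
                           decrease_freq = stats::median(d$decrease_freq),
                           n = nrow(d))))
  rownames(per_generation) <- rownames(decrease_frequency) <- NULL
  list(per_generation = per_generation,
       decrease_frequency = decrease_frequency)
}

#' MSC-type census of eligible capillaries
#'
#' Frequency of occurrence of the four topological configurations among
#' the given capillaries, with per-type median baseline flow and,
#' optionally, median supplied tissue volume and median DA-to-AV path
#' count through the capillary.
#'
#' @param g an [mvn_graph()].
#' @param baseline baseline flow field.
#' @param vessel_ids capillaries to classify (e.g. from
#'   [select_msc_candidates()]).
#' @param tissue optional [supplied_tissue_volume()] result.
#' @param paths optional [count_paths()] result.
#' @return data.frame `type`, `n`, `frequency`, `median_flow`, and when
#'   available `median_supplied_volume`, `median_path_count`.
#' @export
msc_type_census <- function(g, baseline, vessel_ids, tissue = NULL,
                            paths = NULL) {
  inc <- incidence_list(g)
  types <- vapply(vessel_ids, function(v)
    classify_msc_type(g, baseline, v, inc = inc) %||% NA_character_, character(1))
  keep <- !is.na(types)
  d <- data.frame(vessel = vessel_ids[keep], type = types[keep],
                  stringsAsFactors = FALSE)
  q <- abs(flow_of(baseline, g))
  res <- do.call(rbind, lapply(split(d, d$type), function(dd) {
    vi <- match(dd$vessel, g$vessels$id)
    out <- data.frame(type = dd$type[1], n = nrow(dd),
                      frequency = nrow(dd) / nrow(d),
                      median_flow = stats::median(q[vi]))
    if (!is.null(tissue)) {
      out$median_supplied_volume <-
        stats::median(tissue$volume[as.character(dd$vessel)])
    }
    if (!is.null(paths)) {
      out$median_path_count <-
        stats::median(paths$edge_paths[as.character(dd$vessel)], na.rm = TRUE)
    }
    out
  }))
  rownames(res) <- NULL
  res
}
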