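#' Analysis cutoffs used throughout the pipeline
#'
#' @param contact enzyme-PET contact cutoff (A).
#' @param water pocket-water radius from the serine O-gamma (A).
#' @param bound bound/bulk PET partition cutoff (A).
#' @param reactive reactive-state cutoff (A, strict).
#' @param activity d3 activity threshold (A).
#' @param probe SASA probe radius (A).
#' @param sasa_points Shrake-Rupley points per atom.
#' @return named list of cutoffs.
#' @export
pipeline_cutoffs <- function(contact = 5, water = 6, bound = 8, reactive = 5,
                             activity = 5, probe = 1.4, sasa_points = 960) {
  cut <- list(contact = contact, water = water, bound = bound,
              reactive = reactive, activity = activity, probe = probe,
              sasa_points = sasa_points)
  if (any(unlist(cut) <= 0)) stop("all cutoffs must be positive")
  cut
}

#' Aggregate per-replica series or scalars into mean and SD
#'
#' Pointwise mean and sample standard deviation (n - 1 denominator)
#' across replicas, the convention used for all reported traces.
#'
#' @param series list with one numeric vector (or scalar) per replica, or
#'   a plain numeric vector of per-replica scalars.
#' @return object of class `replica_summary`: list with `per_replica`,
#'   `mean`, `sd`, `n_replicas`.
#' @export
aggregate_replicas <- function(series) {
  if (is.numeric(series)) series <- as.list(series)
  if (length(series) < 1) stop("need at least one replica")
  len <- lengths(series)
  if (length(unique(len)) != 1)
    stop("replica series have different lengths: ", paste(len, collapse = ", "))
  m <- do.call(cbind, series)
  structure(list(per_replica = series, mean = rowMeans(m),
                 sd = apply(m, 1, stats::sd), n_replicas = length(series)),
            class = "replica_summary")
}

#' @export
print.replica_summary <- function(x, ...) {
  cat(sprintf("replica_summary: %d replicas, length %d; mean of means %.4g\n",
              x$n_replicas, length(x$mean), mean(x$mean)))
  invisible(x)
}

#' Signed percent change between two condition summaries
#'
#' `100 * (b - a) / a`, with first-order (delta-method) propagation of the
#' two standard deviations assuming independence.
#'
#' @param a,b scalar summaries: `replica_summary` objects (their scalar
#'   mean is used), `list(mean =, sd =)`, or bare numbers (sd 0).
#' @return list with `percent` and `sd`.
#' @export
percent_change <- function(a, b) {
  as_ms <- function(x) {
    if (inherits(x, "replica_summary"))
      list(mean = mean(x$mean), sd = mean(x$sd))
    else if (is.list(x)) list(mean = x$mean, sd = x$sd %||% 0)
    else list(mean = as.numeric(x), sd = 0)
  }
  a <- as_ms(a); b <- as_ms(b)
  if (abs(a$mean) < .Machine$double.eps)
    stop("zero baseline: percent change undefined")
  pct <- 100 * (b$mean - a$mean) / a$mean
  sd <- 100 * sqrt(b$sd^2 / a$mean^2 + (b$mean^2 * a$sd^2) / a$mean^4)
  list(percent = pct, sd = sd)
}

#' Analyse one replica trajectory
#'
#' Runs every binding-site and substrate metric on a single trajectory:
#' RMSD/RMSF, d1-d4, state classification, reactive states, pocket
#' waters, binding-site SASA, per-residue contacts, the residue distance
#' map and the conformer table. Stages whose inputs are absent (no
#' waters, no PET, single frame) are skipped with a warning and returned
#' as `NULL`.
#'
#' @param traj a [pet_trajectory()].
#' @param site a [site_spec()].
#' @param cutoffs see [pipeline_cutoffs()].
#' @return named list of per-metric results.
#' @export
analyze_trajectory <- function(traj, site, cutoffs = pipeline_cutoffs()) {
  top <- traj$topology
  dists <- compute_site_distances(traj, site)
  state <- classify_activity(dists$d3, threshold = cutoffs$activity)
  reactive <- tryCatch(
    count_reactive_states(traj, site, cutoff = cutoffs$reactive),
    error = function(e) { warning("reactive stage skipped: ", conditionMessage(e)); NULL })
  hydration <- tryCatch(
    count_pocket_waters(traj, site, cutoff = cutoffs$water),
    error = function(e) { warning("hydration stage skipped: ", conditionMessage(e)); NULL })
  sasa <- binding_site_sasa(traj, site, probe = cutoffs$probe,
                            n_points = cutoffs$sasa_points)
  dmap <- residue_distance_map(traj, .resolve_residues(site, top))
  has_pet <- any(top$atoms$resname == "PET")
  contacts <- NULL; conformers <- NULL
  if (has_pet) {
    contacts <- binding_site_contacts(traj, site, cutoff = cutoffs$contact)
    conformers <- conformer_table(traj, site, cutoff = cutoffs$bound)
  } else warning("no PET in topology: contact and conformer stages skipped")
  bb <- select_atoms(top, "name N CA C O", quiet = TRUE)$indices
  rmsd_sel <- if (length(bb) >= 3) "name N CA C O" else "protein and heavy"
  rmsd <- tryCatch(rmsd_series(traj, rmsd_sel),
                   error = function(e) { warning("RMSD stage skipped: ", conditionMessage(e)); NULL })
  rmsf_v <- if (n_frames(traj) < 2) {
    warning("single-frame trajectory: RMSF stage skipped"); NULL
  } else tryCatch({
    ca <- select_atoms(top, "name CA", quiet = TRUE)$indices
    sel <- if (length(ca) >= 3) "name CA" else "protein and heavy"
    rmsf(traj, sel)
  }, error = function(e) { warning("RMSF stage skipped: ", conditionMessage(e)); NULL })
  list(distances = dists, state = state, reactive = reactive,
       hydration = hydration, sasa = sasa, contacts = contacts,
       conformers = conformers, distance_map = dmap,
       rmsd = rmsd, rmsf = rmsf_v)
}

# Scalar summaries of one replica analysis.
.replica_scalars <- function(an) {
  c(active_fraction = an$state$active_fraction,
    reactive_total = if (is.null(an$reactive)) NA_real_ else attr(an$reactive, "total"),
    reactive_per_frame = if (is.null(an$reactive)) NA_real_ else mean(an$reactive$count),
    water_mean = if (is.null(an$hydration)) NA_real_ else mean(an$hydration$count),
    sasa_mean = mean(an$sasa$sasa),
    d1_mean = mean(an$distances$d1), d2_mean = mean(an$distances$d2),
    d3_mean = mean(an$distances$d3), d4_mean = mean(an$distances$d4),
    rmsd_mean = if (is.null(an$rmsd)) NA_real_ else mean(an$rmsd),
    contacts_mean = if (is.null(an$contacts)) NA_real_ else mean(an$contacts$total))
}

#' Analyse one system (several replicas) and aggregate
#'
#' @param trajs list of replica [pet_trajectory()]s.
#' @param site a [site_spec()].
#' @param cutoffs see [pipeline_cutoffs()].
#' @param label,condition report tags.
#' @return object of class `system_summary`: per-replica scalars, their
#'   replica mean/SD, the pooled conformer summary, the mean distance
#'   map, and per-residue contact summaries.
#' @export
analyze_system <- function(trajs, site, cutoffs = pipeline_cutoffs(),
                           label = site$enzyme, condition = "") {
  ans <- lapply(trajs, analyze_trajectory, site = site, cutoffs = cutoffs)
  sc <- do.call(rbind, lapply(ans, .replica_scalars))
  scalars <- data.frame(metric = colnames(sc), mean = colMeans(sc),
                        sd = apply(sc, 2, stats::sd), row.names = NULL)
  conf <- NULL
  if (!is.null(ans[[1]]$conformers))
    conf <- conformer_distribution(lapply(ans, `[[`, "conformers"))
  dmap <- Reduce(`+`, lapply(ans, function(a) unclass(a$distance_map))) / length(ans)
  contact_res <- NULL
  if (!is.null(ans[[1]]$contacts)) {
    resn <- setdiff(colnames(ans[[1]]$contacts), c("frame", "time", "total"))
    per <- sapply(ans, function(a) colMeans(a$contacts[resn]))
    per <- matrix(per, nrow = length(resn), dimnames = list(resn, NULL))
    contact_res <- data.frame(residue = resn, mean = rowMeans(per),
                              sd = apply(per, 1, stats::sd),
                              fraction = rowMeans(per) / sum(rowMeans(per)),
                              row.names = NULL)
  }
  structure(list(label = label, condition = condition,
                 n_replicas = length(trajs), per_replica = sc,
                 scalars = scalars, conformers = conf, distance_map = dmap,
                 contacts = contact_res, replicas = ans),
            class = "system_summary")
}

#' @export
print.system_summary <- function(x, ...) {
  cat("system_summary:", x$label, x$condition, "-", x$n_replicas, "replicas\n")
  print(transform(x$scalars, mean = signif(mean, 4), sd = signif(sd, 3)))
  invisible(x)
}

# Pull one scalar (mean, sd) out of a system_summary.
.sys_scalar <- function(sys, metric) {
  i <- match(metric, sys$scalars$metric)
  list(mean = sys$scalars$mean[i], sd = sys$scalars$sd[i])
}

# Bound-partition trans fraction of a system (mean over replicas).
.sys_bound_trans <- function(sys) {
  cf <- sys$conformers
  if (is.null(cf)) return(list(mean = NA_real_, sd = NA_real_))
  i <- which(cf$partition == "bound" & cf$class == "trans")
  list(mean = cf$mean[i], sd = cf$sd[i])
}

#' Run the full multi-system pipeline
#'
#' Each system entry either points at files (`topology` plus a vector of
#' per-replica `trajectories`) or asks the generator for a synthetic
#' scenario (`generate = scenario_config/preset`, `n_replicas`). All
#' systems are analysed with the same cutoffs; systems sharing an
#' `enzyme` across two conditions are contrasted (percent change of
#' pocket waters, reactive states, SASA, d1 and active fraction, with
#' propagated SD). Deterministic given (config, seed, inputs).
#'
#' @param systems list of system entries; each a list with `enzyme`
#'   (`"IsPETase"`/`"PETaseSM14"`), `condition`, and either
#'   `topology`/`trajectories` (file paths) or `generate`
#'   (a [scenario_config()]) with `n_replicas`.
#' @param cutoffs see [pipeline_cutoffs()].
#' @param stride frame stride applied when reading trajectory files.
#' @param seed base seed for generated systems.
#' @param output_dir if non-`NULL`, delimited text tables and a run log
#'   are written there.
#' @return object of class `pet_report`: list of `system_summary` objects
#'   plus a `contrasts` data.frame and provenance info.
#' @export
run_pipeline <- function(systems, cutoffs = pipeline_cutoffs(), stride = 1L,
                         seed = 1L, output_dir = NULL) {
  if (length(systems) < 1) stop("need at least one system")
  summaries <- vector("list", length(systems))
  for (i in seq_along(systems)) {
    sys <- systems[[i]]
    site <- site_preset(sys$enzyme)
    stage <- paste0(sys$enzyme, " ", sys$condition %||% "")
    trajs <- tryCatch({
      if (!is.null(sys$generate)) {
        nr <- sys$n_replicas %||% 3L
        lapply(seq_len(nr), function(r) {
          scn <- generate_scenario(sys$generate, seed = as.integer(
            (as.numeric(seed) * 7919 + i * 101 + r) %% 2147483647))
          scn$trajectory
        })
      } else {
        top <- read_topology(sys$topology)
        lapply(sys$trajectories, read_trajectory, topology = top,
               stride = stride)
      }
    }, error = function(e) stop("pipeline stage 'input:", stage, "' failed: ",
                                conditionMessage(e)))
    summaries[[i]] <- tryCatch(
      analyze_system(trajs, site, cutoffs, label = sys$enzyme,
                     condition = sys$condition %||% ""),
      error = function(e) stop("pipeline stage 'analyze:", stage, "' failed: ",
                               conditionMessage(e)))
    rm(trajs); gc(verbose = FALSE)
  }
  names(summaries) <- vapply(summaries, function(s)
    paste(s$label, s$condition), character(1))
  contrasts <- .pipeline_contrasts(summaries)
  report <- structure(list(systems = summaries, contrasts = contrasts,
                           cutoffs = cutoffs, seed = seed, stride = stride,
                           version = as.character(utils::packageVersion("pettraj")),
                           timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                      class = "pet_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

.pipeline_contrasts <- function(summaries) {
  labs <- vapply(summaries, `[[`, character(1), "label")
  out <- list()
  for (lab in unique(labs)) {
    grp <- summaries[labs == lab]
    if (length(grp) < 2) next
    a <- grp[[1]]; b <- grp[[2]]
    mk <- function(metric, getter) {
      pc <- tryCatch(percent_change(getter(a), getter(b)),
                     error = function(e) list(percent = NA_real_, sd = NA_real_))
      data.frame(enzyme = lab, metric = metric,
                 baseline = a$condition, versus = b$condition,
                 percent = pc$percent, sd = pc$sd, stringsAsFactors = FALSE)
    }
    out[[lab]] <- rbind(
      mk("pocket_waters", function(s) .sys_scalar(s, "water_mean")),
      mk("reactive_states", function(s) .sys_scalar(s, "reactive_total")),
      mk("binding_site_sasa", function(s) .sys_scalar(s, "sasa_mean")),
      mk("d1", function(s) .sys_scalar(s, "d1_mean")),
      mk("active_fraction", function(s) .sys_scalar(s, "active_fraction")),
      mk("bound_trans_fraction", .sys_bound_trans))
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' @export
print.pet_report <- function(x, ...) {
  cat("pet_report (pettraj", x$version, ") -", length(x$systems), "system(s)\n")
  cat("cutoffs:", paste(names(x$cutoffs), unlist(x$cutoffs), sep = "=",
                        collapse = ", "), "\n")
  for (s in x$systems) print(s)
  if (!is.null(x$contrasts)) {
    cat("condition contrasts (% change):\n")
    print(transform(x$contrasts, percent = signif(percent, 4), sd = signif(sd, 3)))
  }
  invisible(x)
}

#' Write the report tables as delimited text
#'
#' One subdirectory per system with per-frame metric tables, plus
#' `summary.tsv`, `contrasts.tsv` and a provenance `report.txt` (seed,
#' stride, cutoffs, package version) at the top level.
#'
#' @param report a `pet_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, f, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  hdr <- c(paste("pettraj", report$version),
           paste("generated", report$timestamp),
           paste("seed", report$seed), paste("stride", report$stride),
           paste("cutoffs:", paste(names(report$cutoffs), unlist(report$cutoffs),
                                   sep = "=", collapse = " ")))
  writeLines(hdr, file.path(dir, "report.txt"))
  allsc <- list()
  for (nm in names(report$systems)) {
    s <- report$systems[[nm]]
    sd <- file.path(dir, gsub("[^A-Za-z0-9_-]", "_", nm))
    if (!dir.exists(sd)) dir.create(sd)
    sc <- s$scalars; sc$system <- nm
    allsc[[nm]] <- sc
    wt(sc, file.path(sd, "summary.tsv"))
    if (!is.null(s$conformers))
      wt(as.data.frame(s$conformers), file.path(sd, "conformers.tsv"))
    if (!is.null(s$contacts)) wt(s$contacts, file.path(sd, "contacts.tsv"))
    dm <- as.data.frame(s$distance_map)
    dm <- cbind(residue = rownames(s$distance_map), dm)
    wt(dm, file.path(sd, "distance_map.tsv"))
    for (r in seq_along(s$replicas)) {
      an <- s$replicas[[r]]
      wt(an$distances, file.path(sd, sprintf("distances_rep%d.tsv", r)))
      wt(an$reactive, file.path(sd, sprintf("reactive_rep%d.tsv", r)))
      if (!is.null(an$hydration))
        wt(an$hydration, file.path(sd, sprintf("hydration_rep%d.tsv", r)))
      wt(an$sasa, file.path(sd, sprintf("sasa_rep%d.tsv", r)))
    }
  }
  wt(do.call(rbind, c(allsc, make.row.names = FALSE)),
     file.path(dir, "summary.tsv"))
  if (!is.null(report$contrasts)) wt(report$contrasts, file.path(dir, "contrasts.tsv"))
  invisible(dir)
}

#' Default four-system study layout
#'
#' The two enzymes at the two salt concentrations, three replicas each,
#' using the [scenario_preset()] parameters.
#'
#' @param n_frames frames per replica.
#' @param n_replicas replicas per system.
#' @return list of system entries for [run_pipeline()].
#' @export
default_study_systems <- function(n_frames = 1000, n_replicas = 3) {
  out <- list()
  for (enz in c("PETaseSM14", "IsPETase")) {
    for (salt in c("150 mM", "900 mM")) {
      out[[paste(enz, salt)]] <- list(
        enzyme = enz, condition = salt,
        generate = scenario_preset(enz, salt, n_frames = n_frames),
        n_replicas = n_replicas)
    }
  }
  out
}
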