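# End-to-end orchestration: one call reads a structure, builds the network,
# runs the requested analysis and writes all outputs plus a run manifest.

#' Assemble a run configuration
#'
#' @param input Path to a PDB file.
#' @param mode One of `"aci"`, `"hotspots"`, `"pathways"`, `"correlate"`.
#' @param active Active-site selection expression (see [select_nodes()]);
#'   required for `aci`, `hotspots` and `pathways`.
#' @param allosteric Allosteric-site selection; required for `pathways`, and
#'   used as the evaluation truth for `hotspots` when given.
#' @param alpha,cutoff,neighbor_cutoff,n_rounds,seed Analysis parameters
#'   (defaults 3.0, 3.4 Å, 4.5 Å, 10000, 1).
#' @param out Output directory (created if absent).
#' @return A `run_config` list, validated for mode/selection consistency.
#' @export
run_config <- function(input, mode = c("aci", "hotspots", "pathways",
                                       "correlate"),
                       active = NULL, allosteric = NULL,
                       alpha = 3.0, cutoff = 3.4, neighbor_cutoff = 4.5,
                       n_rounds = 10000, seed = 1, out = "allonet-out") {
  mode <- match.arg(mode)
  if (mode %in% c("aci", "hotspots") && is.null(active))
    stop("mode '", mode, "' needs an active-site selection")
  if (mode == "pathways" && (is.null(active) || is.null(allosteric)))
    stop("mode 'pathways' needs both site selections")
  structure(list(input = input, mode = mode, active = active,
                 allosteric = allosteric, alpha = alpha, cutoff = cutoff,
                 neighbor_cutoff = neighbor_cutoff, n_rounds = n_rounds,
                 seed = seed, out = out),
            class = "run_config")
}

#' Execute a configured analysis and write its result bundle
#'
#' Writes, depending on mode: an ACI table (CSV) and a B-factor-encoded PDB;
#' hotspot tables plus an evaluation when the true site is supplied; pathway
#' TSV and importance CSV; or the all-pairs coupling matrix CSV. A
#' `manifest.json` capturing every parameter and the package version makes
#' each bundle reproducible from the manifest alone.
#'
#' @param config A `run_config`.
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Named list of the objects produced, invisibly; paths in
#'   `$files`.
#' @export
allonet_run <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  if (!file.exists(config$input)) stop("input not readable: ", config$input)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  say("reading %s", config$input)
  model <- read_structure(config$input)
  say("building network (cutoff %.2f, alpha %.2f)", config$cutoff,
      config$alpha)
  net <- residue_network(model, cutoff = config$cutoff, alpha = config$alpha)
  files <- character(0)
  res <- list(model = model, net = net)
  pth <- function(f) file.path(config$out, f)

  active <- if (!is.null(config$active))
    select_nodes(model, config$active) else NULL
  allos <- if (!is.null(config$allosteric))
    select_nodes(model, config$allosteric) else NULL

  if (config$mode %in% c("aci", "hotspots")) {
    say("propagating from %d source nodes, %d rounds", length(active),
        config$n_rounds)
    prof <- aci_profile(net, active, n_rounds = config$n_rounds,
                        seed = config$seed)
    res$profile <- prof
    write_aci_csv(prof, pth("aci.csv"), model = model)
    writeLines(write_aci_pdb(model, prof), pth("aci.pdb"))
    files <- c(files, pth("aci.csv"), pth("aci.pdb"))
    if (config$mode == "hotspots") {
      say("clustering hotspots (neighbor cutoff %.2f)",
          config$neighbor_cutoff)
      dmat <- residue_distance_matrix(model)
      hs <- detect_hotspots(prof, dmat,
                            neighbor_cutoff = config$neighbor_cutoff)
      res$hotspots <- hs
      utils::write.csv(as.data.frame(hs), pth("hotspots.csv"),
                       row.names = FALSE)
      files <- c(files, pth("hotspots.csv"))
      if (!is.null(allos)) {
        ev <- evaluate_sites(hs, allos, dmat,
                             contact_radius = config$neighbor_cutoff)
        res$evaluation <- ev
        .write_json(ev, pth("evaluation.json"))
        files <- c(files, pth("evaluation.json"))
      }
    }
  } else if (config$mode == "pathways") {
    say("sampling pathways (%d rounds)", config$n_rounds)
    ens <- sample_pathways(net, source = allos, target = active,
                           n_rounds = config$n_rounds, seed = config$seed)
    res$ensemble <- ens
    pathway_table(ens, pth("pathways.tsv"))
    imp <- residue_importance(ens)
    res$importance <- imp
    utils::write.csv(data.frame(label = imp$labels,
                                importance = unname(imp$importance)),
                     pth("importance.csv"), row.names = FALSE)
    files <- c(files, pth("pathways.tsv"), pth("importance.csv"))
  } else if (config$mode == "correlate") {
    say("all-pairs coupling (%d rounds per source)", config$n_rounds)
    cmap <- pairwise_aci(net, n_rounds = config$n_rounds, seed = config$seed)
    res$coupling <- cmap
    utils::write.csv(as.data.frame(unclass(cmap)), pth("coupling.csv"))
    files <- c(files, pth("coupling.csv"))
  }

  manifest <- list(
    package = "allonet",
    version = as.character(utils::packageVersion("allonet")),
    input = config$input, mode = config$mode,
    active = config$active, allosteric = config$allosteric,
    alpha = config$alpha, cutoff = config$cutoff,
    neighbor_cutoff = config$neighbor_cutoff,
    n_rounds = config$n_rounds, seed = config$seed,
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      2)
  )
  .write_json(manifest, pth("manifest.json"))
  files <- c(files, pth("manifest.json"))
  say("done in %.1fs; %d files in %s", manifest$elapsed_s, length(files),
      config$out)
  res$files <- files
  invisible(res)
}

# minimal JSON writer (flat lists of scalars/vectors); avoids a hard
# dependency for the core package
.write_json <- function(x, file) {
  esc <- function(s) gsub("\"", "\\\\\"", s)
  val <- function(v) {
    if (is.null(v)) return("null")
    if (length(v) == 0) return("[]")
    atom <- function(a) {
      if (is.character(a)) paste0("\"", esc(a), "\"")
      else if (is.logical(a)) tolower(as.character(a))
      else format(a, digits = 15)
    }
    parts <- vapply(v, atom, character(1))
    if (length(parts) == 1) parts else
      paste0("[", paste(parts, collapse = ", "), "]")
  }
  body <- vapply(names(x), function(k)
    paste0("  \"", esc(k), "\": ", val(x[[k]])), character(1))
  writeLines(c("{", paste(body, collapse = ",\n"), "}"), file)
}
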