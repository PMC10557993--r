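#' Read a binary data table from CSV
#'
#' Strict parsing: a header row of unique labels is required and every cell
#' must be 0 or 1; violations are reported with their row and column.
#'
#' @param path CSV file path.
#' @return A tibble of integer 0/1 columns.
#' @export
read_data_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!ncol(df)) abort("no columns parsed; is the header missing?")
  if (anyDuplicated(names(df))) {
    abort(paste0("duplicate header label: ",
                 paste(unique(names(df)[duplicated(names(df))]), collapse = ", ")))
  }
  # a headerless file of 0/1 cells yields column names like "X0", "X1", "X0.1"
  if (all(grepl("^X?[01]([.][0-9]+)?$", names(df)))) {
    abort("header row appears to be missing.")
  }
  for (nm in names(df)) {
    v <- df[[nm]]
    bad <- which(!v %in% c("0", "1"))
    if (length(bad)) {
      abort(paste0("non-binary cell \"", v[bad[1]], "\" at row ", bad[1],
                   ", column \"", nm, "\"."))
    }
    df[[nm]] <- as.integer(v)
  }
  tibble::as_tibble(df)
}

#' Write a binary data table as CSV
#'
#' @param data Data frame of 0/1 columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_data_csv <- function(data, path) {
  check_binary_data(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a network specification (JSON)
#'
#' The format has a `nodes` list and a `cpts` object: per node, `parents` (a
#' list) and `rows`, a mapping from the parent-state bitstring (first parent
#' is the leftmost bit) to the probability of state 1. A root's `rows` is a
#' single-entry mapping (written with the key `"prior"`; any single key is
#' accepted on read). The network is validated on read and violations are
#' raised.
#'
#' @param path JSON file path.
#' @return A [bayes_net()].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(spec$nodes) || is.null(spec$cpts)) {
    abort("network spec must have `nodes` and `cpts` fields.")
  }
  nodes <- unlist(spec$nodes)
  cpts <- list()
  for (nm in nodes) {
    entry <- spec$cpts[[nm]]
    if (is.null(entry)) abort(paste0("spec has no CPT for node ", nm))
    parents <- as.character(unlist(entry$parents))
    rows <- entry$rows
    if (length(parents) == 0L) {
      if (length(rows) != 1L) {
        abort(paste0("node ", nm, " is a root; its CPT must have exactly one row."))
      }
      cpts[[nm]] <- cpt(character(), as.numeric(rows[[1]]))
      next
    }
    keys <- bitstrings(length(parents))
    missing <- setdiff(keys, names(rows))
    if (length(missing)) {
      abort(paste0("node ", nm, " CPT is missing row(s): ",
                   paste(missing, collapse = ", ")))
    }
    cpts[[nm]] <- cpt(parents, vapply(keys, function(k)
      as.numeric(rows[[k]]), numeric(1)))
  }
  net <- bayes_net(cpts)
  v <- validate_network(net)
  if (length(v)) abort(paste0("invalid network spec: ", paste(v, collapse = "; ")))
  net
}

#' Write a network specification (JSON)
#'
#' Round-trips losslessly to at least 12 significant digits.
#'
#' @param net A [bayes_net()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  cpts <- lapply(net$cpts, function(ct) {
    keys <- if (length(ct$parents)) bitstrings(length(ct$parents)) else "prior"
    list(parents = I(as.list(ct$parents)),
         rows = setNames(as.list(ct$prob1), keys))
  })
  spec <- list(nodes = as.list(net$nodes), cpts = cpts)
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the demonstration pipeline end to end
#'
#' Orchestrates the full workflow: build the reference network, simulate a
#' dataset, export the pairwise MI matrix, compute a nudge effect report and
#' scan the dataset for synergistic triplets. Every output file gets a JSON
#' metadata sidecar (`<file>.meta.json`) recording the package version, the
#' seed and the configuration, which suffices to reproduce the artifact.
#'
#' @param out_dir Output directory (created if needed).
#' @param variant Reference-network variant, see [build_reference_network()].
#' @param n Simulated sample size (default 100000).
#' @param nudge_node,nudge_delta Soft intervention to report (default `S2` by
#'   +0.2).
#' @param mi_threshold,permutations,fdr_q Scan parameters (see
#'   [scan_synergy()]). The scan runs on the nine network columns.
#' @param seed Integer seed for every stochastic stage.
#' @return Invisibly, a named list of the artifact paths.
#' @export
run_pipeline <- function(out_dir, variant = "optimized", n = 100000L,
                         nudge_node = "S2", nudge_delta = 0.2,
                         mi_threshold = 0.05, permutations = 1000L,
                         fdr_q = 0.15, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(variant = variant, n = n, nudge_node = nudge_node,
              nudge_delta = nudge_delta, mi_threshold = mi_threshold,
              permutations = permutations, fdr_q = fdr_q, seed = seed)
  sidecar <- function(path) {
    meta <- list(tool = "synergynet",
                 version = as.character(utils::packageVersion("synergynet")),
                 seed = seed, config = cfg)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  paths <- list()

  net <- build_reference_network(variant, seed = seed)
  paths$network <- file.path(out_dir, "network.json")
  write_network(net, paths$network); sidecar(paths$network)

  data <- generate_reference_dataset(net, n, seed = seed + 1L)
  paths$data <- file.path(out_dir, "data.csv")
  write_data_csv(data, paths$data); sidecar(paths$data)

  paths$mi <- file.path(out_dir, "mi_matrix.tsv")
  write_mi_matrix(mi_matrix(data), paths$mi); sidecar(paths$mi)

  eff <- population_effect(net, nudge_node, nudge_delta)
  paths$effect <- file.path(out_dir, "effect.tsv")
  readr::write_tsv(eff, paths$effect); sidecar(paths$effect)

  scan <- scan_synergy(data, mi_threshold = mi_threshold,
                       permutations = permutations, fdr_q = fdr_q,
                       seed = seed + 2L)
  paths$scan <- file.path(out_dir, "triplets.tsv")
  readr::write_tsv(scan, paths$scan); sidecar(paths$scan)

  invisible(paths)
}
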