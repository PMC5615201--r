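# End-to-end orchestration: synthetic cohorts (or user files) -> redness
# scoring -> composition -> rate test -> NJ tree -> phenotype report, with a
# manifest that makes every run reproducible bit-for-bit from its config.

stage_index <- c(simulate = 1L, redness = 2L, atcontent = 3L, rrt = 4L,
                 nj = 5L, phenotypes = 6L)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline from a config
#'
#' Executes the selected stages in a fixed order (`simulate`, `redness`,
#' `atcontent`, `rrt`, `nj`, `phenotypes`), writing one TSV/Newick/JSON
#' output per stage plus a run manifest (`manifest.json`) listing package
#' version, seed, parameters and an MD5 digest of every output. The
#' top-level seed is split into fixed per-stage substreams, so re-running
#' the same config reproduces all stochastic outputs exactly and stages can
#' be re-run independently.
#'
#' @param config a list, or a path to a JSON file holding one. Recognised
#'   fields: `seed` (integer), `out_dir`, `stages` (subset of the stage names
#'   above), and one optional block per stage; see the package vignette for
#'   the full schema and a worked example.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% "pipeline_out"
  stages <- config$stages %||% names(stage_index)
  unknown <- setdiff(stages, names(stage_index))
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  stages <- names(stage_index)[stage_index %in% stage_index[stages]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  outputs <- character(0)
  state <- new.env(parent = emptyenv())
  fail <- function(stage, msg) stop("stage '", stage, "': ", msg, call. = FALSE)
  need_file <- function(stage, path, what) {
    if (is.null(path)) fail(stage, paste0("no ", what, " configured and no ",
                                          "simulated substitute available"))
    if (!file.exists(path)) fail(stage, paste0(what, " not found: ", path))
    path
  }

  for (stage in stages) {
    t0 <- Sys.time()
    message("[", stage, "] starting")
    sseed <- sub_seed(seed, stage_index[[stage]])
    outputs <- c(outputs, switch(stage,
      simulate = pipeline_simulate(config$simulate, out_dir, sseed, state),
      redness = pipeline_redness(config$redness, out_dir, state, need_file),
      atcontent = pipeline_atcontent(config$atcontent, out_dir, state, need_file),
      rrt = pipeline_rrt(config$rrt, out_dir, sseed, state, need_file, fail),
      nj = pipeline_nj(config$nj, out_dir, sseed, state, need_file),
      phenotypes = pipeline_phenotypes(out_dir, state, fail)
    ))
    message(sprintf("[%s] done in %.2fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  manifest <- list(
    package = "beetlesym",
    version = as.character(utils::packageVersion("beetlesym")),
    seed = seed, stages = stages,
    config = config[setdiff(names(config), c("seed", "out_dir", "stages"))],
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_simulate <- function(cfg, out_dir, sseed, state) {
  cfg <- cfg %||% list()
  paths <- character(0)
  if (!is.null(cfg$alignment)) {
    a <- cfg$alignment
    aln <- simulate_alignment(a$tree, model = a$model %||% "k2p",
                              kappa = a$kappa %||% 2,
                              length = a$length %||% 2000,
                              seed = sub_seed(sseed, 1))
    p <- file.path(out_dir, "alignment.fasta")
    write_fasta(apply(unclass(aln), 1, paste0, collapse = ""), p)
    state$alignment_path <- p
    paths <- c(paths, p)
  }
  if (!is.null(cfg$images)) {
    im <- cfg$images
    n <- im$n_per_group %||% 10
    for (grp in c("sym", "apo")) {
      base <- if (grp == "sym") im$base_rgb_sym else im$base_rgb_apo
      idxs <- vapply(seq_len(n), function(i) {
        sim <- simulate_cuticle_image(
          width = im$width %||% 80, height = im$height %||% 80,
          base_rgb = base, noise_sd = im$noise_sd %||% 8,
          highlight_frac = im$highlight_frac %||% 0.05,
          shadow_frac = im$shadow_frac %||% 0.05,
          seed = sub_seed(sseed, 100 * (grp == "apo") + 1 + i))
        p <- file.path(out_dir, sprintf("%s_%02d.png", grp, i))
        write_rgb_png(sim$image, p)
        paths <<- c(paths, p)
        p
      }, character(1))
      state[[paste0("images_", grp)]] <- idxs
    }
  }
  if (!is.null(cfg$weights)) {
    w <- cfg$weights
    n <- w$n %||% 30
    df <- data.frame(
      group = rep(c("sym", "apo"), each = n),
      weight_mg = c(
        simulate_weights(n, w$mean_sym %||% 0.9, w$sd %||% 0.05,
                         seed = sub_seed(sseed, 201)),
        simulate_weights(n, w$mean_apo %||% 0.81, w$sd %||% 0.05,
                         seed = sub_seed(sseed, 202))))
    p <- write_tsv(df, file.path(out_dir, "weights.tsv"))
    state$weights <- df
    paths <- c(paths, p)
  }
  paths
}

pipeline_redness <- function(cfg, out_dir, state, need_file) {
  cfg <- cfg %||% list()
  low <- cfg$low_frac %||% 0.10
  high <- cfg$high_frac %||% 0.10
  score_one <- function(path, rect, group) {
    img <- read_rgb_image(path)
    if (is.null(rect)) rect <- c(0, 0, image_width(img), image_height(img))
    r <- score_image(img, rect, low_frac = low, high_frac = high)
    data.frame(image = basename(path), group = group,
               n_total = r$n_pixels_total, n_used = r$n_pixels_used,
               index = r$index)
  }
  rows <- list()
  if (!is.null(cfg$images)) {
    for (entry in cfg$images) {
      need_file("redness", entry$path, "image")
      rows[[length(rows) + 1L]] <-
        score_one(entry$path, entry$rect, entry$group %||% NA_character_)
    }
  } else {
    for (grp in c("sym", "apo")) {
      for (p in state[[paste0("images_", grp)]])
        rows[[length(rows) + 1L]] <- score_one(p, NULL, grp)
    }
    if (!length(rows))
      need_file("redness", NULL, "image list")
  }
  df <- do.call(rbind, rows)
  state$redness <- df
  write_tsv(df, file.path(out_dir, "redness.tsv"))
}

pipeline_atcontent <- function(cfg, out_dir, state, need_file) {
  cfg <- cfg %||% list()
  path <- need_file("atcontent", cfg$fasta %||% state$alignment_path,
                    "FASTA input")
  df <- composition_table(read_fasta(path))
  write_tsv(df, file.path(out_dir, "atcontent.tsv"))
}

pipeline_rrt <- function(cfg, out_dir, sseed, state, need_file, fail) {
  cfg <- cfg %||% list()
  path <- need_file("rrt", cfg$fasta %||% state$alignment_path,
                    "aligned FASTA input")
  for (f in c("lineage1", "lineage2", "outgroup"))
    if (is.null(cfg[[f]])) fail("rrt", paste0("missing taxon set '", f, "'"))
  res <- relative_rate_test(
    read_alignment(path), cfg$lineage1, cfg$lineage2, cfg$outgroup,
    model = cfg$model %||% "k2p", n_bootstrap = cfg$n_bootstrap %||% 2000,
    seed = sseed)
  df <- data.frame(K1 = res$K1, K2 = res$K2, diff = res$diff,
                   ratio = res$ratio, z = res$z, p = res$p_two_sided,
                   n_sites = res$n_sites, n_bootstrap = res$n_bootstrap)
  write_tsv(df, file.path(out_dir, "rrt.tsv"))
}

pipeline_nj <- function(cfg, out_dir, sseed, state, need_file) {
  cfg <- cfg %||% list()
  path <- need_file("nj", cfg$fasta %||% state$alignment_path,
                    "aligned FASTA input")
  tree <- bootstrap_nj(read_alignment(path), model = cfg$model %||% "k2p",
                       n_reps = cfg$n_reps %||% 1000, seed = sseed)
  out <- file.path(out_dir, "nj_tree.nwk")
  write_newick(tree, out)
  out
}

pipeline_phenotypes <- function(out_dir, state, fail) {
  rows <- list()
  if (!is.null(state$redness)) {
    r <- state$redness
    rows[[length(rows) + 1L]] <- compare_phenotypes(
      r$index[r$group == "sym"], r$index[r$group == "apo"],
      label = "redness_index")
  }
  if (!is.null(state$weights)) {
    w <- state$weights
    rows[[length(rows) + 1L]] <- compare_phenotypes(
      w$weight_mg[w$group == "sym"], w$weight_mg[w$group == "apo"],
      label = "dry_weight_mg")
  }
  if (!length(rows))
    fail("phenotypes", "needs the redness and/or simulate stages upstream")
  write_tsv(do.call(rbind, rows), file.path(out_dir, "phenotypes.tsv"))
}
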