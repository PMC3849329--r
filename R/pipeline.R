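#' Run the full carbon accounting pipeline
#'
#' Ties the stages together: obtain plot inventories (from CSV directories
#' or the synthetic generator), build the carbon stock ledger and deltas,
#' the spatial clustering diagnostics, the accumulation trajectories, and
#' the landscape analysis (scene rendering or loading, canopy delineation,
#' gridding, encroachment accounting and the plot-vs-image comparison),
#' writing every artifact plus a machine-readable run manifest into
#' `out_dir`. Stages whose inputs are missing are skipped with a warning,
#' along with their dependents.
#'
#' @param config A named list or path to a YAML file with (all optional
#'   unless noted): `seed` (integer, required for synthetic stages),
#'   `plots` (named list: each entry either `list(dir = "path/to/csvs")`
#'   or `list(fixture = "HD")` or a full set of [stand_config()]
#'   arguments), `reference_plot` (default "HSC" when present),
#'   `landscape` (`fixture`/config for the 25-ha scene, `threshold`,
#'   `min_area_m2`, `cell_m`, `span_years`, `mask_cutoff_year`),
#'   `accumulation` (`end_year`, `initial_understory_c`).
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with every computed artifact (`inventories`,
#'   `stock_table`, `deltas`, `spatial`, `trajectories`, `landscape`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  res <- list()

  inventories <- list()
  for (nm in names(config$plots)) {
    spec <- config$plots[[nm]]
    inv <- if (!is.null(spec$dir)) {
      read_inventory_csv(spec$dir, plot_id = nm)
    } else {
      cfg <- if (!is.null(spec$fixture)) {
        fixture_config(spec$fixture, seed = seed)
      } else {
        do.call(stand_config, c(list(seed = seed), spec))
      }
      st <- generate_stand(cfg, plot_id = nm)
      sample_soil(sample_cover(st))
    }
    inventories[[nm]] <- inv
  }
  res$inventories <- inventories

  if (length(inventories)) {
    have_covers <- vapply(inventories, function(i) {
      !is.null(i$covers) && nrow(i$covers) > 0
    }, logical(1))
    if (all(have_covers)) {
      res$stock_table <- plot_carbon_table(inventories)
      write_stock_table_csv(res$stock_table,
                            file.path(out_dir, "stock_table.csv"))
      ref <- config$reference_plot
      if (is.null(ref) && "HSC" %in% names(inventories)) ref <- "HSC"
      if (!is.null(ref) && ref %in% names(inventories)) {
        res$deltas <- stock_deltas(res$stock_table, ref)
        utils::write.csv(res$deltas$per_plot,
                         file.path(out_dir, "stock_deltas.csv"),
                         row.names = FALSE)
      }
    } else {
      warning("some plots lack cover observations: ",
              "stock table and deltas skipped")
    }

    sp <- lapply(inventories, function(inv) {
      ok_cores <- !is.null(inv$cores) && nrow(inv$cores) > 0
      if (!ok_cores && nrow(inv$trees) < 3) {
        warning("plot ", inv$plot_id,
                ": no cores and < 3 trees, spatial stats skipped")
        return(NULL)
      }
      spatial_summary(inv)
    })
    sp <- do.call(rbind, sp[!vapply(sp, is.null, logical(1))])
    if (!is.null(sp)) {
      res$spatial <- sp
      utils::write.csv(sp, file.path(out_dir, "spatial_summary.csv"),
                       row.names = FALSE)
    }

    acc <- config$accumulation
    end_year <- if (is.null(acc$end_year)) 2005 else acc$end_year
    init_u <- if (is.null(acc$initial_understory_c)) {
      0.416
    } else {
      acc$initial_understory_c
    }
    traj <- list()
    for (nm in names(inventories)) {
      tr <- inventories[[nm]]$trees
      if (nrow(tr) && all(is.finite(tr$establishment_year))) {
        traj[[nm]] <- accumulation_trajectory(
          tr, area_m2 = prod(inventories[[nm]]$extent_m),
          end_year = end_year, initial_understory_c = init_u
        )
      }
    }
    if (length(traj)) {
      res$trajectories <- traj
      tidy <- do.call(rbind, lapply(names(traj), function(nm) {
        write_trajectory_csv(traj[[nm]], nm)
      }))
      utils::write.csv(tidy, file.path(out_dir, "trajectories.csv"),
                       row.names = FALSE)
    }
  }

  ls_cfg <- config$landscape
  if (!is.null(ls_cfg)) {
    scene <- if (!is.null(ls_cfg$scene_tsv)) {
      read_scene_tsv(ls_cfg$scene_tsv)
    } else {
      cfg <- if (!is.null(ls_cfg$fixture)) {
        fixture_config(ls_cfg$fixture, seed = seed)
      } else {
        do.call(stand_config, c(list(seed = seed), ls_cfg$stand))
      }
      st <- generate_stand(cfg, plot_id = "landscape")
      render_scene(
        st,
        mask_cutoff_year = if (is.null(ls_cfg$mask_cutoff_year)) {
          1937
        } else {
          ls_cfg$mask_cutoff_year
        }
      )
    }
    thr <- if (is.null(ls_cfg$threshold)) 0.5 else ls_cfg$threshold
    min_a <- if (is.null(ls_cfg$min_area_m2)) 1 else ls_cfg$min_area_m2
    cmap <- canopy_map_carbon(delineate_canopies(scene, thr, min_a))
    cell <- if (is.null(ls_cfg$cell_m)) c(15, 20) else unlist(ls_cfg$cell_m)
    grid <- grid_canopy_summary(cmap, cell)
    span <- if (is.null(ls_cfg$span_years)) 69 else ls_cfg$span_years
    account <- if (!is.null(scene$mask) && any(scene$mask == 1)) {
      encroachment_account(cmap, scene, span)
    } else {
      warning("no historical mask: encroachment account skipped")
      NULL
    }
    comparison <- NULL
    if (!is.null(res$stock_table)) {
      enc <- setdiff(unique(res$stock_table$plot),
                     config$reference_plot %||% "HSC")
      plot_mg <- vapply(enc, function(p) {
        kg <- res$stock_table$kg_c_m2[res$stock_table$plot == p &
                                        res$stock_table$pool == "pj_tree"]
        scale_plot_to_landscape(kg * prod(inventories[[p]]$extent_m),
                                prod(inventories[[p]]$extent_m),
                                attr(cmap, "extent_ha"))
      }, numeric(1))
      img_mg <- attr(cmap, "total_kg_c") / 1000
      if (length(plot_mg) && img_mg > 0) {
        comparison <- list(plot_estimates_mg = plot_mg,
                           image_estimate_mg = img_mg,
                           percent_difference =
                             method_comparison(plot_mg, img_mg))
      }
    }
    res$landscape <- list(scene = scene, canopies = cmap, grid = grid,
                          account = account, comparison = comparison)
    utils::write.csv(as.data.frame(cmap),
                     file.path(out_dir, "canopies.csv"), row.names = FALSE)
    utils::write.csv(grid, file.path(out_dir, "grid_summary.csv"),
                     row.names = FALSE)
    if (!is.null(account)) {
      utils::write.csv(as.data.frame(account),
                       file.path(out_dir, "encroachment_account.csv"),
                       row.names = FALSE)
    }
  }

  manifest <- list(
    package = "pjcarbon",
    version = as.character(utils::packageVersion("pjcarbon")),
    seed = seed,
    config = config,
    r_version = R.version.string,
    artifacts = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  res$manifest <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
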