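# Column schemas for the canonical CSV inputs. Units are fixed by contract
# (documented per reader) and never auto-converted.
table_schemas <- list(
  exposure  = c(region_id = "c", casrn = "c", mean = "d", sd = "d"),
  age       = c(region_id = "c", age_lo = "i", age_hi = "i", count = "d"),
  obesity   = c(region_id = "c", prev = "d", ci_lo = "d", ci_hi = "d"),
  ir        = c(age_lo = "i", age_hi = "i", ir_mean = "d", ir_sd = "d"),
  css       = c(casrn = "c", age_group = "c", weight_status = "c", css = "d"),
  conc_resp = c(casrn = "c", assay = "c", conc = "d", resp = "d")
)

stop_rows <- function(msg, rows) {
  stop(msg, " (rows ", paste(utils::head(rows, 10), collapse = ", "),
       if (length(rows) > 10) ", ..." else "", ")", call. = FALSE)
}

validate_table <- function(df, schema) {
  switch(schema,
    exposure = {
      if (any(bad <- df$mean < 0)) stop_rows("negative exposure mean", which(bad))
      if (any(bad <- df$sd < 0)) stop_rows("negative exposure sd", which(bad))
    },
    age = {
      if (any(bad <- df$count < 0)) stop_rows("negative age-bin count", which(bad))
      if (any(bad <- df$age_hi < df$age_lo)) {
        stop_rows("age_hi below age_lo", which(bad))
      }
      by_region <- split(df, df$region_id)
      for (rid in names(by_region)) {
        b <- by_region[[rid]][order(by_region[[rid]]$age_lo), ]
        if (nrow(b) > 1 && any(b$age_lo[-1] <= b$age_hi[-nrow(b)])) {
          stop("overlapping age bins in region ", rid, call. = FALSE)
        }
        if (sum(b$count) <= 0) {
          stop("region ", rid, " has no population in any age bin",
               call. = FALSE)
        }
      }
    },
    obesity = {
      bad <- !(df$ci_lo <= df$prev & df$prev <= df$ci_hi &
                 df$ci_lo >= 0 & df$ci_hi <= 100)
      if (any(bad)) stop_rows("obesity CI out of order or out of [0,100]",
                              which(bad))
    },
    ir = {
      if (any(bad <- df$ir_mean <= 0)) stop_rows("non-positive ir_mean", which(bad))
      if (any(bad <- df$ir_sd < 0)) stop_rows("negative ir_sd", which(bad))
      b <- df[order(df$age_lo), ]
      if (b$age_lo[1] != 0 || b$age_hi[nrow(b)] < 100 ||
          (nrow(b) > 1 && any(b$age_lo[-1] != b$age_hi[-nrow(b)] + 1L))) {
        stop("inhalation-rate brackets must partition ages 0-100",
             call. = FALSE)
      }
    },
    css = {
      if (any(bad <- df$css < 0)) stop_rows("negative Css sample", which(bad))
      cells <- unique(df[c("casrn", "age_group", "weight_status")])
      full <- expand.grid(casrn = unique(df$casrn),
                          age_group = unique(df$age_group),
                          weight_status = unique(df$weight_status),
                          stringsAsFactors = FALSE)
      have <- paste(cells$casrn, cells$age_group, cells$weight_status)
      need <- paste(full$casrn, full$age_group, full$weight_status)
      miss <- setdiff(need, have)
      if (length(miss) > 0) {
        stop("Css table missing strata: ", paste(miss, collapse = "; "),
             call. = FALSE)
      }
    },
    conc_resp = {
      if (any(bad <- df$conc < 0)) stop_rows("negative concentration", which(bad))
      counts <- tapply(df$conc[df$conc > 0],
                       paste(df$casrn, df$assay)[df$conc > 0],
                       function(x) length(unique(x)))
      if (any(counts < 4)) {
        stop("fewer than 4 distinct positive concentrations for: ",
             paste(names(counts)[counts < 4], collapse = "; "),
             call. = FALSE)
      }
    }
  )
  invisible(df)
}

#' Read a validated input table
#'
#' Reads one of the canonical CSV inputs and applies its schema validation.
#' Files that violate any invariant are rejected whole — no partially loaded
#' table is ever returned. Canonical snake_case headers are required;
#' there is no fuzzy header matching.
#'
#' Schemas (units are fixed by contract):
#' * `exposure`: `region_id, casrn, mean, sd` — ug/m3.
#' * `age`: `region_id, age_lo, age_hi, count` — years (inclusive bins),
#'   persons.
#' * `obesity`: `region_id, prev, ci_lo, ci_hi` — percent.
#' * `ir`: `age_lo, age_hi, ir_mean, ir_sd` — m3/day/kg; brackets must
#'   partition ages 0-100.
#' * `css`: `casrn, age_group, weight_status, css` — uM per mg/kg/day, one
#'   row per stored toxicokinetic sample; every stratum cell must be present
#'   for every chemical.
#' * `conc_resp`: `casrn, assay, conc, resp` — uM and percent activity; at
#'   least 4 distinct positive concentrations per chemical-by-assay.
#'
#' @param path CSV file path.
#' @param schema One of `"exposure"`, `"age"`, `"obesity"`, `"ir"`, `"css"`,
#'   `"conc_resp"`.
#' @return A validated tibble.
#' @export
read_table <- function(path, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  spec <- table_schemas[[schema]]
  collectors <- lapply(spec, function(code) {
    switch(code, c = readr::col_character(), d = readr::col_double(),
           i = readr::col_integer())
  })
  # vroom warns (redundantly) when a named parser has no column; the
  # missing-column check below turns that case into a schema error
  df <- withCallingHandlers(
    readr::read_csv(
      path,
      col_types = do.call(readr::cols,
                          c(collectors, .default = list(readr::col_guess()))),
      show_col_types = FALSE
    ),
    warning = function(w) {
      if (inherits(w, "vroom_mismatched_column_name")) {
        invokeRestart("muffleWarning")
      }
    }
  )
  readr::stop_for_problems(df)
  missing_cols <- setdiff(names(spec), names(df))
  if (length(missing_cols) > 0) {
    stop("`", path, "` missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!stats::complete.cases(df[names(spec)]))) {
    stop("`", path, "` contains missing values", call. = FALSE)
  }
  validate_table(df, schema)
  df
}

#' Read region polygons from GeoJSON
#'
#' Reads an RFC 7946 FeatureCollection; each feature must carry a region
#' identifier property. Coordinates are taken as-is (WGS84 assumed; no
#' reprojection). Geometries are kept as lists of polygon rings (each ring a
#' two-column coordinate matrix) and checked structurally: rings closed,
#' at least four points.
#'
#' @param path GeoJSON file.
#' @param id_property Name of the identifier property. Default `"region_id"`.
#' @return Tibble with `region_id` and a `geometry` list-column, in file
#'   order.
#' @export
read_regions <- function(path, id_property = "region_id") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("`", path, "` is not a GeoJSON FeatureCollection", call. = FALSE)
  }
  feats <- gj$features
  if (length(feats) == 0) {
    warning("empty FeatureCollection", call. = FALSE)
    return(tibble::tibble(region_id = character(0), geometry = list()))
  }
  ids <- character(length(feats))
  geoms <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    id <- f$properties[[id_property]]
    if (is.null(id)) {
      stop("feature ", i, " missing ", id_property, call. = FALSE)
    }
    ids[i] <- as.character(id)
    geoms[i] <- list(parse_geojson_geometry(f$geometry, feature = i))
  }
  if (anyDuplicated(ids)) stop("duplicate region ids", call. = FALSE)
  tibble::tibble(region_id = ids, geometry = geoms)
}

# Parse a GeoJSON Polygon/MultiPolygon into a list of ring matrices.
parse_geojson_geometry <- function(g, feature = NA) {
  if (is.null(g)) return(NULL)
  ring_to_matrix <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt) {
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
    }))
    if (nrow(m) < 4 || !all(m[1, ] == m[nrow(m), ])) {
      stop("feature ", feature, ": ring not closed or fewer than 4 points",
           call. = FALSE)
    }
    m
  }
  if (g$type == "Polygon") {
    lapply(g$coordinates, ring_to_matrix)
  } else if (g$type == "MultiPolygon") {
    unlist(lapply(g$coordinates, function(poly) {
      lapply(poly, ring_to_matrix)
    }), recursive = FALSE)
  } else {
    stop("feature ", feature, ": unsupported geometry type ", g$type,
         call. = FALSE)
  }
}

geometry_to_geojson <- function(rings) {
  if (is.null(rings)) return(NULL)
  list(type = "Polygon",
       coordinates = lapply(rings, function(m) {
         lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
       }))
}

#' Write regional summaries as a GeoJSON choropleth source
#'
#' Attaches metric quantiles as feature properties (named like
#' `GCA.Eff_q50`) to the region polygons and writes an RFC 7946
#' FeatureCollection.
#'
#' @param summaries Tibble from [summarize_region()] (columns `region_id`,
#'   `metric`, `prob`, `value`; an `assay` column, if present, must have one
#'   level).
#' @param regions Region tibble from [read_regions()] or [gen_regions()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_region_results <- function(summaries, regions, path) {
  unknown <- setdiff(unique(summaries$region_id), regions$region_id)
  if (length(unknown) > 0) {
    stop("summaries reference unknown regions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(summaries$value))) {
    stop("non-finite summary values cannot be written", call. = FALSE)
  }
  wide <- summaries |>
    dplyr::mutate(prop = sprintf("%s_q%g", .data$metric,
                                 round(100 * .data$prob))) |>
    dplyr::select("region_id", "prop", "value") |>
    tidyr::pivot_wider(names_from = "prop", values_from = "value")
  feats <- lapply(seq_len(nrow(regions)), function(i) {
    rid <- regions$region_id[i]
    props <- c(list(region_id = rid))
    j <- match(rid, wide$region_id)
    if (!is.na(j)) {
      for (nm in setdiff(names(wide), "region_id")) {
        props[[nm]] <- wide[[nm]][j]
      }
    }
    list(type = "Feature",
         properties = props,
         geometry = geometry_to_geojson(regions$geometry[[i]]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Serialize a state to a directory
#'
#' Writes every populated tabular field as CSV plus a JSON manifest (field
#' names, dimensions, configuration, seed). Population matrices are written
#' long per region. The companion [read_state()] restores a field-for-field
#' equal state.
#'
#' @param state A `mixrisk_state`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_state <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    readr::write_csv(df, file.path(dir, paste0(name, ".csv")))
  }
  for (nm in c("exposure", "age", "obesity", "ir", "css", "conc_resp",
               "hill_params", "responses", "region_summary", "multi_assay",
               "sensitivity")) {
    if (!is.null(state[[nm]])) wr(state[[nm]], nm)
  }
  if (!is.null(state$regions)) {
    empty <- tibble::tibble(region_id = character(0), metric = character(0),
                            prob = numeric(0), value = numeric(0))
    write_region_results(empty, state$regions, file.path(dir, "regions.geojson"))
  }
  if (!is.null(state$population)) {
    pop <- purrr::map_dfr(state$population, population_to_long)
    wr(pop, "population")
  }
  manifest <- list(
    package = "mixrisk",
    config = unclass(state$config),
    fields = as.list(populated_fields(state)),
    n_regions = if (is.null(state$regions)) 0L else nrow(state$regions),
    chemicals = state$chemicals$casrn
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

population_to_long <- function(p) {
  chems <- colnames(p$c_ext)
  base <- tibble::tibble(
    region_id = p$region_id,
    individual = seq_len(p$n),
    age = p$age, obese = p$obese, ir = p$ir
  )
  mats <- purrr::map_dfr(chems, function(ch) {
    tibble::tibble(
      region_id = p$region_id, individual = seq_len(p$n), casrn = ch,
      c_ext = p$c_ext[, ch], d_int = p$d_int[, ch],
      css = p$css[, ch], c_invitro = p$c_invitro[, ch]
    )
  })
  dplyr::left_join(mats, base, by = c("region_id", "individual")) |>
    dplyr::select("region_id", "individual", "age", "obese", "ir", "casrn",
                  "c_ext", "d_int", "css", "c_invitro")
}

long_to_population <- function(df) {
  split(df, df$region_id) |>
    lapply(function(d) {
      chems <- sort(unique(d$casrn))
      n <- max(d$individual)
      first <- d[d$casrn == chems[1], ]
      first <- first[order(first$individual), ]
      mk <- function(col) {
        m <- matrix(NA_real_, n, length(chems),
                    dimnames = list(NULL, chems))
        for (ch in chems) {
          dd <- d[d$casrn == ch, ]
          m[dd$individual, ch] <- dd[[col]]
        }
        m
      }
      structure(
        list(region_id = first$region_id[1], n = n,
             age = as.integer(first$age), obese = first$obese,
             ir = first$ir, c_ext = mk("c_ext"), d_int = mk("d_int"),
             css = mk("css"), c_invitro = mk("c_invitro")),
        class = "mixrisk_population"
      )
    })
}

#' Restore a serialized state
#'
#' @param dir Directory written by [write_state()].
#' @return A `mixrisk_state`.
#' @export
read_state <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(risk_config, manifest$config)
  rd <- function(name, schema = NULL) {
    f <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(f)) return(NULL)
    if (!is.null(schema)) read_table(f, schema)
    else readr::read_csv(f, show_col_types = FALSE)
  }
  regions <- if (file.exists(file.path(dir, "regions.geojson"))) {
    read_regions(file.path(dir, "regions.geojson"))
  } else NULL
  st <- risk_state(config = cfg, regions = regions,
                   exposure = rd("exposure", "exposure"),
                   age = rd("age", "age"),
                   obesity = rd("obesity", "obesity"),
                   ir = rd("ir", "ir"),
                   css = rd("css", "css"),
                   conc_resp = rd("conc_resp", "conc_resp"))
  st$hill_params <- rd("hill_params")
  st$responses <- rd("responses")
  st$region_summary <- rd("region_summary")
  st$multi_assay <- rd("multi_assay")
  st$sensitivity <- rd("sensitivity")
  pop <- rd("population")
  if (!is.null(pop)) st$population <- long_to_population(pop)
  validate_state(st)
  st
}
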