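# Parameter presets. The three LC-strength columns of the small-network
# (N = 5 per population) parameter table emulate developmental stages:
# no LC connectivity (infant), moderate (adolescent), strong (adult).
# Large-network (N = 500) presets use the rescaled strength table; membrane
# constants and noise scales are not re-printed there and are inherited
# from the small-network No-LC column for every case (an assumption; with
# the raised SA noise of the small LC-bearing columns, the tiny rescaled
# LC strengths cannot offset the systematic SA drive advantage at large N
# and the network locks into sleep). The N = 50 preset reuses the
# large-network strengths at intermediate size and is flagged as
# interpolated.

.make_specs <- function(n, p_wa, p_sa, p_wp, n_wp = n) {
  list(WA = population_spec("WA", n, noise_scale = p_wa),
       SA = population_spec("SA", n, noise_scale = p_sa),
       WP = population_spec("WP", n_wp, noise_scale = p_wp))
}

.n5_conn <- function(wp_wa, wp_wp, wa_wp, sa_wp, mi = 24) {
  connectivity_matrix(wa_wa = 6, sa_sa = 6, wa_sa = mi, sa_wa = mi,
                      wp_wa = wp_wa, wp_wp = wp_wp,
                      wa_wp = wa_wp, sa_wp = sa_wp)
}

.n500_conn <- function(wp_wa, wp_wp, wa_wp, sa_wp, wa_wa = 0.8) {
  connectivity_matrix(wa_wa = wa_wa, sa_sa = 0.8, wa_sa = 17, sa_wa = 17,
                      wp_wa = wp_wa, wp_wp = wp_wp,
                      wa_wp = wa_wp, sa_wp = sa_wp)
}

.preset <- function(name, description, specs, conn, recommended_steps) {
  structure(
    list(name = name, description = description, specs = specs,
         conn = conn, constants = membrane_constants(-70, -55),
         recommended_steps = as.integer(recommended_steps)),
    class = "sleep_preset"
  )
}

.build_presets <- function() {
  p <- list()

  p[["n5-no-lc"]] <- .preset(
    "n5-no-lc", "Small network, no LC connectivity (infant stage)",
    .make_specs(5, 1.05, 1.05, 1.0),
    .n5_conn(0, 0, 0, 0), 1e6)
  p[["n5-moderate-lc"]] <- .preset(
    "n5-moderate-lc", "Small network, moderate LC connectivity (adolescent)",
    .make_specs(5, 1.05, 1.08, 1.0),
    .n5_conn(wp_wa = 3, wp_wp = 2, wa_wp = 2, sa_wp = 2), 1e6)
  p[["n5-strong-lc"]] <- .preset(
    "n5-strong-lc", "Small network, strong LC connectivity (adult)",
    .make_specs(5, 1.05, 1.08, 1.0),
    .n5_conn(wp_wa = 4, wp_wp = 2, wa_wp = 3, sa_wp = 3), 1e6)

  # mutual-inhibition variants of the no-LC network (75/100/125% of 24)
  p[["n5-weak-mi"]] <- .preset(
    "n5-weak-mi", "No-LC small network, mutual inhibition at 75% (18)",
    .make_specs(5, 1.05, 1.05, 1.0), .n5_conn(0, 0, 0, 0, mi = 18), 1e6)
  p[["n5-moderate-mi"]] <- .preset(
    "n5-moderate-mi", "No-LC small network, mutual inhibition at 100% (24)",
    .make_specs(5, 1.05, 1.05, 1.0), .n5_conn(0, 0, 0, 0, mi = 24), 1e6)
  p[["n5-strong-mi"]] <- .preset(
    "n5-strong-mi", "No-LC small network, mutual inhibition at 125% (30)",
    .make_specs(5, 1.05, 1.05, 1.0), .n5_conn(0, 0, 0, 0, mi = 30), 1e6)

  p[["n500-no-lc"]] <- .preset(
    "n500-no-lc",
    "Large network, no LC (membrane/noise inherited from the small network)",
    .make_specs(500, 1.05, 1.05, 1.0), .n500_conn(0, 0, 0, 0), 1e5)
  p[["n500-moderate-lc"]] <- .preset(
    "n500-moderate-lc",
    "Large network, moderate LC (membrane/noise inherited)",
    .make_specs(500, 1.05, 1.05, 1.0),
    .n500_conn(wp_wa = 0.1, wp_wp = 0.05, wa_wp = 0.1, sa_wp = 0.1), 1e5)
  p[["n500-strong-lc"]] <- .preset(
    "n500-strong-lc",
    "Large network, strong LC (membrane/noise inherited)",
    .make_specs(500, 1.05, 1.05, 1.0),
    .n500_conn(wp_wa = 0.2, wp_wp = 0.1, wa_wp = 0.2, sa_wp = 0.2), 1e5)
  p[["n500-wa-increase"]] <- .preset(
    "n500-wa-increase",
    "Large network, no LC but raised WA self-excitation (control)",
    .make_specs(500, 1.05, 1.05, 1.0),
    .n500_conn(0, 0, 0, 0, wa_wa = 1.1), 1e5)

  p[["n50-strong-lc"]] <- .preset(
    "n50-strong-lc",
    "Intermediate network; large-network strengths at N = 50 (interpolated)",
    .make_specs(50, 1.05, 1.05, 1.0),
    .n500_conn(wp_wa = 0.2, wp_wp = 0.1, wa_wp = 0.2, sa_wp = 0.2), 2e5)

  # legacy two-population systems: mutual inhibition only, no
  # self-excitation, the WP population silent (all strengths and noise 0)
  p[["legacy-two-pop-n1"]] <- .preset(
    "legacy-two-pop-n1",
    "Two mutually inhibiting single neurons; WP inert",
    .make_specs(1, 1.05, 1.05, 0),
    connectivity_matrix(wa_sa = 24, sa_wa = 24), 1e5)
  p[["legacy-two-pop-n10"]] <- .preset(
    "legacy-two-pop-n10",
    "Two populations of 10, all-to-all mutual inhibition only; WP inert",
    .make_specs(10, 1.05, 1.05, 0, n_wp = 1),
    connectivity_matrix(wa_sa = 24, sa_wa = 24), 1e5)

  p
}

.preset_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- .build_presets()
    cache
  }
})

#' Names of the registered parameter presets
#'
#' @return Character vector of preset names usable with [get_preset()].
#' @export
preset_names <- function() names(.preset_registry())

#' Retrieve a registered parameter preset
#'
#' Presets bundle population specs, the connectivity matrix, membrane
#' constants and a recommended simulation length. Small-network (`n5-*`)
#' presets carry the published small-network parameter columns; `n500-*`
#' and `n50-*` use the rescaled large-network strengths; `legacy-*` are
#' the earlier two-population mutual-inhibition-only systems.
#'
#' @param name One of [preset_names()].
#' @return A fresh `"sleep_preset"` object (modifying it never affects the
#'   registry).
#' @examples
#' conn_strength(get_preset("n5-strong-lc")$conn, "LC", "WA")  # 4
#' @export
get_preset <- function(name) {
  reg <- .preset_registry()
  if (!name %in% names(reg))
    stop("unknown preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  # a deep copy: presets contain only atomic fields, so unserialize-free
  # duplication via rapply-style reconstruction is unnecessary in R's
  # copy-on-write semantics, but return a rebuilt object to be explicit
  pre <- reg[[name]]
  structure(list(name = pre$name, description = pre$description,
                 specs = pre$specs, conn = pre$conn,
                 constants = pre$constants,
                 recommended_steps = pre$recommended_steps),
            class = "sleep_preset")
}

#' @export
print.sleep_preset <- function(x, ...) {
  cat(sprintf("<sleep_preset> %s\n  %s\n", x$name, x$description))
  cat(sprintf("  N = (%s); recommended steps = %d\n",
              paste(vapply(x$specs, `[[`, integer(1), "size"),
                    collapse = ", "),
              x$recommended_steps))
  invisible(x)
}

# ---- dotted parameter paths ----------------------------------------------

.path_aliases <- function(path) {
  if (path == "conn.mutual_inhibition")
    return(c("conn.WA.SA", "conn.SA.WA"))
  path
}

#' Return a preset with one numeric parameter replaced
#'
#' Paths are dotted: `conn.<SRC>.<TGT>` (e.g. `conn.WP.WA`),
#' `specs.<POP>.<field>` (e.g. `specs.SA.noise_scale`),
#' `constants.rmp` / `constants.threshold`, or the alias
#' `conn.mutual_inhibition`, which sets `conn.WA.SA` and `conn.SA.WA`
#' together.
#'
#' @param preset A `"sleep_preset"`.
#' @param path Dotted parameter path.
#' @param value Replacement numeric value.
#' @return A modified copy of the preset.
#' @examples
#' p <- preset_with(get_preset("n5-no-lc"), "conn.mutual_inhibition", 18)
#' conn_strength(p$conn, "WA", "SA")  # 18
#' @export
preset_with <- function(preset, path, value) {
  stopifnot(inherits(preset, "sleep_preset"))
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("replacement value must be a single finite number")
  for (pth in .path_aliases(path)) {
    parts <- strsplit(pth, ".", fixed = TRUE)[[1]]
    if (parts[1] == "conn" && length(parts) == 3L) {
      m <- unclass(preset$conn)
      m[.norm_pop(parts[2]), .norm_pop(parts[3])] <- value
      preset$conn <- validate_connectivity(m)
    } else if (parts[1] == "specs" && length(parts) == 3L) {
      pop <- .norm_pop(parts[2])
      sp <- preset$specs[[pop]]
      if (!parts[3] %in% c("size", "capacitance", "tau", "noise_scale"))
        stop("unknown population field '", parts[3], "'")
      args <- sp[c("name", "size", "capacitance", "tau", "noise_scale")]
      args[[parts[3]]] <- value
      preset$specs[[pop]] <- do.call(population_spec, args)
    } else if (parts[1] == "constants" && length(parts) == 2L) {
      cst <- preset$constants
      if (!parts[2] %in% c("rmp", "threshold"))
        stop("unknown membrane constant '", parts[2], "'")
      cst[[parts[2]]] <- value
      preset$constants <- membrane_constants(cst$rmp, cst$threshold)
    } else if (pth == "recommended_steps") {
      preset$recommended_steps <- as.integer(value)
    } else {
      stop("cannot resolve parameter path '", pth, "'")
    }
  }
  preset
}

# ---- flat key-path config files ------------------------------------------

.preset_kv <- function(preset) {
  kv <- c(name = preset$name,
          description = preset$description,
          recommended_steps = preset$recommended_steps)
  for (pop in POPULATIONS) {
    sp <- preset$specs[[pop]]
    for (f in c("size", "capacitance", "tau", "noise_scale"))
      kv[[paste("specs", pop, f, sep = ".")]] <- format(sp[[f]])
  }
  for (src in POPULATIONS) for (tgt in POPULATIONS) {
    if (src == "WP" && tgt == "SA") next  # structurally absent
    kv[[paste("conn", src, tgt, sep = ".")]] <-
      format(unclass(preset$conn)[src, tgt])
  }
  kv[["constants.rmp"]] <- format(preset$constants$rmp)
  kv[["constants.threshold"]] <- format(preset$constants$threshold)
  kv
}

#' Write a preset as a flat `key.path: value` text file
#'
#' @param preset A `"sleep_preset"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(preset, path) {
  kv <- .preset_kv(preset)
  writeLines(paste0(names(kv), ": ", unname(kv)), path)
  invisible(path)
}

#' Read a preset back from a flat config file
#'
#' Accepts the format written by [write_config()]: one `key.path: value`
#' pair per line, `#` comments ignored.
#'
#' @param path Config file path.
#' @return A `"sleep_preset"` object.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(m, `[`, character(1), 2)
  vals <- vapply(m, `[`, character(1), 3)
  kv <- setNames(vals, trimws(keys))

  num <- function(k, default = NULL) {
    if (!k %in% names(kv)) {
      if (is.null(default)) stop("config is missing key '", k, "'")
      return(default)
    }
    as.numeric(kv[[k]])
  }
  specs <- setNames(lapply(POPULATIONS, function(pop) {
    population_spec(pop,
                    size = num(paste0("specs.", pop, ".size")),
                    capacitance = num(paste0("specs.", pop, ".capacitance"), 1),
                    tau = num(paste0("specs.", pop, ".tau"), 15),
                    noise_scale = num(paste0("specs.", pop, ".noise_scale"), 0))
  }), POPULATIONS)
  m3 <- matrix(0, 3, 3, dimnames = list(POPULATIONS, POPULATIONS))
  for (src in POPULATIONS) for (tgt in POPULATIONS) {
    if (src == "WP" && tgt == "SA") next
    m3[src, tgt] <- num(paste("conn", src, tgt, sep = "."), 0)
  }
  .preset(
    name = if ("name" %in% names(kv)) kv[["name"]] else "custom",
    description = if ("description" %in% names(kv)) kv[["description"]]
                  else "read from config",
    specs = specs,
    conn = validate_connectivity(m3),
    recommended_steps = num("recommended_steps", 1e5)
  ) -> pre
  pre$constants <- membrane_constants(num("constants.rmp", -70),
                                      num("constants.threshold", -55))
  pre
}
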