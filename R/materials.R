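#' Library of prosthetic materials and their thermal time constants
#'
#' Bench measurements of the thermal time constant \eqn{\tau} (minutes) for
#' nine commonly used liner, sock and socket materials tested individually,
#' and for six liner + socket combinations measured at the liner interface.
#' Liner materials vary widely (0.6--3.6 min) while socket shells cluster
#' around 4--4.5 min; stacking a liner under a socket slows the response
#' further (4.1--6.7 min). The defaults ship as plain CSV under
#' `inst/extdata/` and can be replaced by user files of the same layout.
#'
#' @param materials_path,combinations_path Optional paths to CSV files with
#'   columns `name,kind,thickness_mm,tau_min` and
#'   `liner,socket,combo_tau_min`; defaults are the packaged tables.
#'
#' @return A list of class `material_library` with tibbles `materials`
#'   (name, kind, thickness_mm, tau_min) and `combinations`
#'   (liner, socket, combo_tau_min).
#' @export
#' @examples
#' lib <- material_library()
#' get_material("Pe-lite")
#' get_stack("Pe-lite", "thermoplastic")$combo_tau_min
material_library <- function(materials_path = NULL, combinations_path = NULL) {
  materials_path <- materials_path %||%
    system.file("extdata", "materials.csv", package = "prosthermal")
  combinations_path <- combinations_path %||%
    system.file("extdata", "material_combinations.csv", package = "prosthermal")
  mats <- readr::read_csv(materials_path, show_col_types = FALSE, progress = FALSE)
  combos <- readr::read_csv(combinations_path, show_col_types = FALSE, progress = FALSE)
  validate_materials(mats)
  validate_combinations(combos, mats)
  structure(list(materials = mats, combinations = combos),
            class = "material_library")
}

validate_materials <- function(mats) {
  need <- c("name", "kind", "thickness_mm", "tau_min")
  if (!all(need %in% names(mats))) {
    abort(paste0("materials table must have columns: ", paste(need, collapse = ", ")),
          class = "prosthermal_validation_error")
  }
  if (!all(mats$kind %in% c("liner", "socket", "sock"))) {
    abort("material kind must be one of liner/socket/sock",
          class = "prosthermal_validation_error")
  }
  if (any(mats$thickness_mm <= 0) || any(mats$tau_min <= 0)) {
    abort("thickness_mm and tau_min must be positive",
          class = "prosthermal_validation_error")
  }
  invisible(mats)
}

validate_combinations <- function(combos, mats) {
  need <- c("liner", "socket", "combo_tau_min")
  if (!all(need %in% names(combos))) {
    abort(paste0("combinations table must have columns: ", paste(need, collapse = ", ")),
          class = "prosthermal_validation_error")
  }
  if (any(combos$combo_tau_min <= 0)) {
    abort("combo_tau_min must be positive", class = "prosthermal_validation_error")
  }
  invisible(combos)
}

#' @export
print.material_library <- function(x, ...) {
  cat("<material_library>\n$materials\n")
  print(x$materials)
  cat("\n$combinations\n")
  print(x$combinations)
  invisible(x)
}

#' @rdname material_library
#' @param name Material name; matching is exact but case-insensitive.
#' @param library A `material_library`; the packaged default when `NULL`.
#' @return `get_material()` returns a one-row tibble (a single material).
#' @export
get_material <- function(name, library = NULL) {
  library <- library %||% material_library()
  hit <- library$materials[tolower(library$materials$name) == tolower(name), ]
  if (nrow(hit) != 1) {
    abort(sprintf("unknown material '%s'", name),
          class = "prosthermal_validation_error")
  }
  hit
}

#' @rdname material_library
#' @param liner,socket Names of the liner and socket layers.
#' @return `get_stack()` returns a [stack_spec()] for the named pair.
#' @export
get_stack <- function(liner, socket, library = NULL) {
  library <- library %||% material_library()
  lin <- get_material(liner, library)
  soc <- get_material(socket, library)
  hit <- library$combinations[
    tolower(library$combinations$liner) == tolower(liner) &
      tolower(library$combinations$socket) == tolower(socket), ]
  stack_spec(lin, soc,
             combo_tau_min = if (nrow(hit) == 1) hit$combo_tau_min else NULL)
}

#' Specify a liner + socket stack
#'
#' @param liner,socket One-row material tibbles (see [get_material()]) with
#'   `kind` "liner" and "socket" respectively.
#' @param combo_tau_min Measured time constant (minutes) of the combination
#'   at the liner interface; `NULL` when not measured.
#' @return A list of class `stack_spec`.
#' @export
stack_spec <- function(liner, socket, combo_tau_min = NULL) {
  if (!identical(liner$kind, "liner")) {
    abort("`liner` must be a liner material", class = "prosthermal_validation_error")
  }
  if (!identical(socket$kind, "socket")) {
    abort("`socket` must be a socket material", class = "prosthermal_validation_error")
  }
  if (!is.null(combo_tau_min) && (!is.numeric(combo_tau_min) || combo_tau_min <= 0)) {
    abort("combo_tau_min must be positive", class = "prosthermal_validation_error")
  }
  structure(list(liner = liner, socket = socket, combo_tau_min = combo_tau_min),
            class = "stack_spec")
}

#' @export
print.stack_spec <- function(x, ...) {
  cat(sprintf("<stack_spec: %s + %s, combo tau = %s min>\n",
              x$liner$name, x$socket$name,
              if (is.null(x$combo_tau_min)) "unmeasured" else
                format(x$combo_tau_min)))
  invisible(x)
}
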