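#' Phycobiliprotein classes and their bilin stoichiometry
#'
#' The three phycobiliprotein (PBP) classes differ in how many bilin
#' chromophores each alpha and beta subunit carries: allophycocyanin (AP)
#' binds 1 + 1 phycocyanobilin (PCB) per alpha-beta protomer, phycocyanin
#' (PC) 1 + 2 PCB, and phycoerythrin (PE) 2 + 3 bilins of the
#' phycoerythrobilin/phycourobilin (PEB/PUB) family.
#'
#' @param name One of `"AP"`, `"PC"`, `"PE"`.
#' @return An object of class `pbp_class` with fields `name`,
#'   `bilins_per_alpha`, `bilins_per_beta` and `bilin_types`.
#' @examples
#' pbp_class("PC")$bilins_per_beta  # 2
#' @export
pbp_class <- function(name = c("AP", "PC", "PE")) {
  name <- match.arg(name)
  def <- switch(name,
    AP = list(a = 1L, b = 1L, types = "PCB"),
    PC = list(a = 1L, b = 2L, types = "PCB"),
    PE = list(a = 2L, b = 3L, types = c("PEB", "PUB")))
  structure(list(name = name,
                 bilins_per_alpha = def$a,
                 bilins_per_beta  = def$b,
                 bilin_types      = def$types),
            class = "pbp_class")
}

#' Define a structural element of a phycobilisome
#'
#' An element is a core cylinder, a rod, or an auxiliary hexamer position,
#' holding an ordered stack of PBP trimers. Hexamers are represented as two
#' stacked trimers, so `n_trimers` for one (alpha-beta)_6 hexamer is 2.
#'
#' @param id Unique element label (e.g. `"A"`, `"R1"`, `"Rx1"`).
#' @param kind `"core_cylinder"`, `"rod"` or `"auxiliary_hexamer"`.
#' @param stacks A data frame (or list coercible to one) with columns
#'   `class` (PBP class name) and `n_trimers` (positive integer).
#' @return An object of class `pbs_element`.
#' @export
structural_element <- function(id, kind = c("core_cylinder", "rod", "auxiliary_hexamer"),
                               stacks) {
  kind <- match.arg(kind)
  stacks <- as.data.frame(stacks, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "n_trimers") %in% names(stacks)))
  if (!all(stacks$class %in% c("AP", "PC", "PE")))
    stop_pbsq("unknown PBP class in element '", id, "'")
  if (!all(stacks$n_trimers >= 1))
    stop_pbsq("n_trimers must be >= 1 in element '", id, "'")
  structure(list(id = as.character(id), kind = kind,
                 stacks = stacks[, c("class", "n_trimers")]),
            class = "pbs_element")
}

#' Assemble a phycobilisome composition model
#'
#' @param elements List of [structural_element()] objects with unique ids.
#' @param name Model label.
#' @return Object of class `pbs_composition`.
#' @seealso [gvipbs_composition()] for the default bundle-shaped model,
#'   [count_trimers()], [count_bilins()], [bilin_census()].
#' @export
composition_model <- function(elements, name = "custom") {
  stopifnot(is.list(elements))
  if (length(elements) && !all(vapply(elements, inherits, TRUE, "pbs_element")))
    stop_pbsq("all elements must be created by structural_element()")
  ids <- vapply(elements, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_pbsq("element ids must be unique")
  structure(list(name = name, elements = elements), class = "pbs_composition")
}

hexamer_stack <- function(class, n_hexamers) {
  data.frame(class = class, n_trimers = 2L * as.integer(n_hexamers))
}

#' Default composition of the bundle-shaped Gloeobacter violaceus PBS
#'
#' Builds the composite model of the G. violaceus phycobilisome: a
#' pentacylindrical AP core with 14 modelled (alpha-beta)_3 trimers
#' (A/A' cylinders with 3 trimers each, B with 4, C/C' with 2 each — the
#' fourth trimer of the bottom cylinders is absent from the composite
#' model), six rods in two bundles carrying 18 PC and 14 PE hexamers
#' (R1/R1'/R3/R3': 3 PC + 2 PE hexamers each; R2/R2': 3 PC + 3 PE), and
#' two auxiliary PC hexamers (Rx1/Rx1') belting the core.
#'
#' @param include_tentative_rx Logical; if `TRUE` adds the tentative
#'   Rx2/Rx2'/Rx3/Rx3' auxiliary PC hexamers, which are not part of the
#'   composite model, for what-if censuses. Default `FALSE`.
#' @return A `pbs_composition` with 82 trimers and 864 bilins by default.
#' @examples
#' m <- gvipbs_composition()
#' count_trimers(m)  # 82
#' count_bilins(m)   # 864
#' @export
gvipbs_composition <- function(include_tentative_rx = FALSE) {
  core <- function(id, n) structural_element(id, "core_cylinder",
    data.frame(class = "AP", n_trimers = n))
  rod <- function(id, n_pc, n_pe) structural_element(id, "rod",
    rbind(hexamer_stack("PC", n_pc), hexamer_stack("PE", n_pe)))
  aux <- function(id) structural_element(id, "auxiliary_hexamer",
    hexamer_stack("PC", 1L))
  el <- list(
    core("A", 3L), core("A'", 3L), core("B", 4L), core("C", 2L), core("C'", 2L),
    rod("R1", 3L, 2L), rod("R1'", 3L, 2L),
    rod("R2", 3L, 3L), rod("R2'", 3L, 3L),
    rod("R3", 3L, 2L), rod("R3'", 3L, 2L),
    aux("Rx1"), aux("Rx1'"))
  if (include_tentative_rx)
    el <- c(el, list(aux("Rx2"), aux("Rx2'"), aux("Rx3"), aux("Rx3'")))
  composition_model(el, name = if (include_tentative_rx)
    "GviPBS composite + tentative Rx" else "GviPBS composite")
}

stack_table <- function(model) {
  if (!length(model$elements))
    return(data.frame(element = character(), kind = character(),
                      class = character(), n_trimers = integer()))
  do.call(rbind, lapply(model$elements, function(e)
    data.frame(element = e$id, kind = e$kind, class = e$stacks$class,
               n_trimers = e$stacks$n_trimers, stringsAsFactors = FALSE)))
}

#' Count phycobiliprotein trimers in a composition model
#'
#' @param model A `pbs_composition`.
#' @return Integer total of (alpha-beta)_3 trimers (hexamers count as 2).
#' @export
count_trimers <- function(model) {
  stopifnot(inherits(model, "pbs_composition"))
  sum(stack_table(model)$n_trimers)
}

#' Count bilin chromophores in a composition model
#'
#' Each trimer holds three alpha-beta protomers; each protomer carries
#' `bilins_per_alpha + bilins_per_beta` bilins of its PBP class.
#'
#' @inheritParams count_trimers
#' @return Integer total bilin count.
#' @export
count_bilins <- function(model) {
  sum(bilin_census(model))
}

#' Bilin census broken down by phycobiliprotein class
#'
#' @inheritParams count_trimers
#' @return Named integer vector over classes AP, PC, PE; sums to
#'   [count_bilins()].
#' @export
bilin_census <- function(model) {
  stopifnot(inherits(model, "pbs_composition"))
  tab <- stack_table(model)
  out <- c(AP = 0L, PC = 0L, PE = 0L)
  for (cl in names(out)) {
    p <- pbp_class(cl)
    n <- sum(tab$n_trimers[tab$class == cl])
    out[cl] <- as.integer(n * 3L * (p$bilins_per_alpha + p$bilins_per_beta))
  }
  out
}

#' Per-element census summary
#'
#' @inheritParams count_trimers
#' @return Data frame with one row per element: id, kind, trimers, bilins.
#' @export
census_by_element <- function(model) {
  stopifnot(inherits(model, "pbs_composition"))
  rows <- lapply(model$elements, function(e) {
    sub <- composition_model(list(e), name = e$id)
    data.frame(element = e$id, kind = e$kind,
               trimers = count_trimers(sub), bilins = count_bilins(sub),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(element = character(), kind = character(),
                      trimers = integer(), bilins = integer()))
  do.call(rbind, rows)
}

#' @export
print.pbs_composition <- function(x, ...) {
  cat("PBS composition model:", x$name, "\n")
  cat("  elements:", length(x$elements),
      " trimers:", count_trimers(x),
      " bilins:", count_bilins(x), "\n")
  cen <- bilin_census(x)
  cat("  bilins by class: ", paste(names(cen), cen, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Read or write a composition model as a YAML config file
#'
#' The config carries one record per structural element (`id`, `kind`,
#' `stacks` with PBP class and trimer count), so models round-trip through
#' a human-editable file.
#'
#' @param model A `pbs_composition` (for writing).
#' @param path File path.
#' @return `read_composition()` returns a `pbs_composition`;
#'   `write_composition()` returns `path` invisibly.
#' @export
write_composition <- function(model, path) {
  stopifnot(inherits(model, "pbs_composition"))
  rec <- list(name = model$name, elements = lapply(model$elements, function(e)
    list(id = e$id, kind = e$kind,
         stacks = lapply(seq_len(nrow(e$stacks)), function(i)
           list(class = e$stacks$class[i],
                n_trimers = as.integer(e$stacks$n_trimers[i]))))))
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' @rdname write_composition
#' @export
read_composition <- function(path) {
  rec <- yaml::read_yaml(path)
  if (is.null(rec$elements)) stop_pbsq("config has no 'elements' section")
  el <- lapply(rec$elements, function(e) {
    st <- do.call(rbind, lapply(e$stacks, function(s)
      data.frame(class = s$class, n_trimers = as.integer(s$n_trimers))))
    structural_element(e$id, e$kind, st)
  })
  composition_model(el, name = rec$name %||% "unnamed")
}
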