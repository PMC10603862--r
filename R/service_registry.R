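#' @title Microservice registration
#'
#' @description Each microservice is described by a nine-parameter record:
#' name, description, framework, dependencies, input ports, output port,
#' category, license and invoke path. Descriptors are validated, stored as
#' triples in the \code{services} partition of the knowledge space, and
#' looked up by name or by port kinds. Names must be unique ("legible":
#' non-empty, at most 64 characters, alphanumeric/underscore/hyphen).
#'
#' This implementation restricts ports to exactly one primary data input and
#' exactly one output, because composition is a linear chain; multi-input
#' fan-in is a non-goal.
#'
#' @name service_registry
NULL

#' Construct a typed port specification
#' @param name Port name (non-empty).
#' @param data_kind One of [data_kinds()].
#' @export
port <- function(name, data_kind) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is_data_kind(data_kind)) {
    stop("unknown data kind: ", data_kind, call. = FALSE)
  }
  list(name = name, data_kind = data_kind)
}

#' Construct a dependency record
#' @param id Library identifier (non-empty).
#' @param install_uri Where the library can be installed from (stored, never
#'   executed).
#' @param version Version string.
#' @export
dependency <- function(id, install_uri = "", version = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  list(id = id, install_uri = as.character(install_uri),
       version = as.character(version))
}

DESCRIPTOR_FIELDS <- c("name", "description", "framework", "dependencies",
                       "inputs", "outputs", "category", "license",
                       "invoke_path")

.name_legible <- function(name) {
  is.character(name) && length(name) == 1L && !is.na(name) &&
    nzchar(name) && nchar(name) <= 64L && grepl("^[A-Za-z0-9_-]+$", name)
}

#' Validate a registration record
#'
#' Checks that all nine parameters are present and well-formed and returns a
#' \code{service_descriptor}. On failure, signals a condition of class
#' \code{sf_validation_error} whose \code{fields} attribute names every
#' missing or malformed parameter.
#'
#' @param record Named list with the nine descriptor fields. \code{inputs}
#'   and \code{outputs} are lists of [port()]s (a single port may be given
#'   bare); \code{dependencies} a list of [dependency()] records (may be
#'   empty).
#' @return A validated object of class \code{service_descriptor}.
#' @export
validate_descriptor <- function(record) {
  bad <- character(0)
  get <- function(f) if (f %in% names(record)) record[[f]] else NULL

  missing <- setdiff(DESCRIPTOR_FIELDS, names(record))
  bad <- c(bad, missing)

  chr1 <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
  if (!"name" %in% missing && !.name_legible(get("name"))) bad <- c(bad, "name")
  for (f in c("description", "framework", "category", "license",
              "invoke_path")) {
    if (!f %in% missing && !chr1(get(f))) bad <- c(bad, f)
  }

  norm_ports <- function(x) {
    if (is.list(x) && !is.null(x$name) && !is.null(x$data_kind)) x <- list(x)
    x
  }
  ok_port <- function(p) {
    is.list(p) && chr1(p$name) && nzchar(p$name) && is_data_kind(p$data_kind)
  }
  inputs <- norm_ports(get("inputs")); outputs <- norm_ports(get("outputs"))
  if (!"inputs" %in% missing &&
      (!is.list(inputs) || length(inputs) < 1L ||
       !all(vapply(inputs, ok_port, TRUE)))) bad <- c(bad, "inputs")
  if (!"outputs" %in% missing &&
      (!is.list(outputs) || length(outputs) != 1L ||
       !all(vapply(outputs, ok_port, TRUE)))) bad <- c(bad, "outputs")

  deps <- get("dependencies")
  ok_dep <- function(d) is.list(d) && chr1(d$id) && nzchar(d$id)
  if (!"dependencies" %in% missing &&
      (!is.list(deps) || (length(deps) > 0L &&
       !all(vapply(deps, ok_dep, TRUE))))) bad <- c(bad, "dependencies")

  if (length(bad)) {
    bad <- unique(bad)
    cond <- structure(
      class = c("sf_validation_error", "error", "condition"),
      list(message = paste0("invalid descriptor; bad or missing parameters: ",
                            paste(sort(bad), collapse = ", ")),
           call = sys.call(-1), fields = bad))
    stop(cond)
  }

  deps <- lapply(deps, function(d) dependency(d$id, d$install_uri %||% "",
                                              d$version %||% ""))
  structure(list(
    name = record$name, description = record$description,
    framework = record$framework, dependencies = deps,
    inputs = lapply(inputs, function(p) port(p$name, p$data_kind)),
    outputs = lapply(outputs, function(p) port(p$name, p$data_kind)),
    category = record$category, license = record$license,
    invoke_path = record$invoke_path), class = "service_descriptor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Primary input / output data kind of a descriptor
#' @param d A \code{service_descriptor}.
#' @export
service_input_kind <- function(d) d$inputs[[1]]$data_kind

#' @rdname service_input_kind
#' @export
service_output_kind <- function(d) d$outputs[[1]]$data_kind

.svc_subj <- function(name) paste0("service/", name)

#' Convert a descriptor to triples
#' @param d A validated \code{service_descriptor}.
#' @return Data frame of triples for the \code{services} partition.
#' @export
descriptor_to_triples <- function(d) {
  subj <- .svc_subj(d$name)
  tr <- list(
    triple(subj, "a", "Service"),
    triple(subj, "hasName", lit(d$name)),
    triple(subj, "hasDescription", lit(d$description)),
    triple(subj, "hasFramework", lit(d$framework)),
    triple(subj, "hasCategory", lit(d$category)),
    triple(subj, "hasLicense", lit(d$license)),
    triple(subj, "hasInvokePath", lit(d$invoke_path)))
  node_triples <- function(items, link, prefix, fields) {
    out <- list()
    for (i in seq_along(items)) {
      node <- paste0(subj, "/", prefix, "/", i)
      out <- c(out, list(triple(subj, link, node),
                         triple(node, "index", lit(as.numeric(i)))))
      for (f in names(fields)) {
        out <- c(out, list(triple(node, fields[[f]],
                                  lit(as.character(items[[i]][[f]])))))
      }
    }
    out
  }
  tr <- c(tr,
    node_triples(d$dependencies, "hasDependency", "dep",
                 c(id = "depId", install_uri = "depInstallUri",
                   version = "depVersion")),
    node_triples(d$inputs, "hasInputPort", "in",
                 c(name = "portName", data_kind = "portKind")),
    node_triples(d$outputs, "hasOutputPort", "out",
                 c(name = "portName", data_kind = "portKind")))
  do.call(rbind, tr)
}

.node_field <- function(df, node, pred) {
  v <- df$o[df$s == node & df$p == pred]
  if (length(v) != 1L) stop("descriptor reconstruction: missing ", pred,
                            " on ", node, call. = FALSE)
  v
}

#' Reconstruct a descriptor from the services partition
#' @param space A knowledge space.
#' @param name Registered service name.
#' @export
descriptor_from_triples <- function(space, name) {
  df <- space$partitions$services
  subj <- .svc_subj(name)
  if (!any(df$s == subj & df$p == "hasName")) {
    stop("no registered service named '", name, "'", call. = FALSE)
  }
  field <- function(pred) .node_field(df, subj, pred)
  read_nodes <- function(link, fields) {
    nodes <- df$o[df$s == subj & df$p == link]
    if (!length(nodes)) return(list())
    idx <- vapply(nodes, function(nd)
      as.numeric(.node_field(df, nd, "index")), 0)
    nodes <- nodes[order(idx)]
    lapply(nodes, function(nd) {
      out <- lapply(fields, function(pred) .node_field(df, nd, pred))
      names(out) <- names(fields)
      out
    })
  }
  record <- list(
    name = field("hasName"), description = field("hasDescription"),
    framework = field("hasFramework"), category = field("hasCategory"),
    license = field("hasLicense"), invoke_path = field("hasInvokePath"),
    dependencies = read_nodes("hasDependency",
      c(id = "depId", install_uri = "depInstallUri", version = "depVersion")),
    inputs = read_nodes("hasInputPort",
      c(name = "portName", data_kind = "portKind")),
    outputs = read_nodes("hasOutputPort",
      c(name = "portName", data_kind = "portKind")))
  validate_descriptor(record)
}

#' Register a microservice
#'
#' Validates the record and writes its triples into the \code{services}
#' partition. Registration is atomic: on any failure (including a duplicate
#' name) the space is returned unchanged by the error path — the caller's
#' copy is never touched.
#'
#' @param space A knowledge space.
#' @param record Registration record (see [validate_descriptor()]), or an
#'   already-validated descriptor.
#' @return List with elements \code{space} (updated) and \code{descriptor}.
#' @export
register_service <- function(space, record) {
  d <- if (inherits(record, "service_descriptor")) record
       else validate_descriptor(record)
  if (d$name %in% registry_names(space)) {
    stop("duplicate service name: '", d$name,
         "' is already registered", call. = FALSE)
  }
  space <- ks_add_triples(space, "services", descriptor_to_triples(d))
  list(space = space, descriptor = d)
}

#' Names of all registered services
#' @param space A knowledge space.
#' @export
registry_names <- function(space) {
  df <- space$partitions$services
  sort(df$o[df$p == "hasName" & df$o_kind == "string"])
}

#' All registered descriptors
#' @param space A knowledge space.
#' @return Named list of \code{service_descriptor}s, sorted by name.
#' @export
registry_descriptors <- function(space) {
  nm <- registry_names(space)
  ds <- lapply(nm, descriptor_from_triples, space = space)
  names(ds) <- nm
  ds
}

#' Find services by port kinds and category
#'
#' At least one filter must be bound; all bound filters must match. Category
#' matching is case-insensitive substring-free exact comparison.
#'
#' @param space A knowledge space.
#' @param input_kind,output_kind Optional data kinds.
#' @param category Optional category text.
#' @return List of matching descriptors, sorted by name.
#' @export
find_services <- function(space, input_kind = NULL, output_kind = NULL,
                          category = NULL) {
  if (is.null(input_kind) && is.null(output_kind) && is.null(category)) {
    stop("at least one filter must be bound", call. = FALSE)
  }
  ds <- registry_descriptors(space)
  keep <- vapply(ds, function(d) {
    (is.null(input_kind) || service_input_kind(d) == input_kind) &&
      (is.null(output_kind) || service_output_kind(d) == output_kind) &&
      (is.null(category) || tolower(d$category) == tolower(category))
  }, TRUE)
  ds[keep]
}

#' @export
print.service_descriptor <- function(x, ...) {
  cat(sprintf("<service> %s [%s -> %s] (%s)\n", x$name,
              service_input_kind(x), service_output_kind(x), x$category))
  invisible(x)
}
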