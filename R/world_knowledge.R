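#' @title World knowledge
#'
#' @description Reusable facts derived from tasks, stored in the
#' \code{world} partition. The chief kind is a feature-selection fact: the
#' feature subset an optimizer selected for a given table schema, which is
#' reused — the optimizer stage replaced by a column projection — whenever a
#' later task arrives with exactly the same ordered column names. Answer
#' facts (text topic to answer, with a human reward) and image-vector facts
#' (numeric vector to label) are stored and retrieved losslessly.
#'
#' @name world_knowledge
NULL

#' Construct a feature-selection fact
#' @param schema_key Ordered column names of the table the fact was learned
#'   on.
#' @param selected_features Non-empty subset of \code{schema_key}.
#' @param source_policy Identifier of the policy record the fact came from.
#' @param metric Accuracy (or similar) achieved with the selected subset.
#' @export
feature_fact <- function(schema_key, selected_features,
                         source_policy = "unknown", metric = NA_real_) {
  stopifnot(is.character(schema_key), length(schema_key) >= 1L,
            is.character(selected_features), length(selected_features) >= 1L)
  if (!all(selected_features %in% schema_key)) {
    stop("selected features are not a subset of the schema", call. = FALSE)
  }
  structure(list(schema_key = schema_key,
                 selected_features = selected_features,
                 source_policy = source_policy,
                 metric = as.numeric(metric)), class = "feature_fact")
}

.schema_fact_id <- function(schema_key) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(as.character(jsonlite::toJSON(schema_key)), tf, eos = NULL)
  paste0("fact/features/", unname(tools::md5sum(tf)))
}

#' Record a feature-selection fact
#' @param space A knowledge space.
#' @param fact A [feature_fact()].
#' @return The updated space.
#' @export
record_feature_fact <- function(space, fact) {
  stopifnot(inherits(fact, "feature_fact"))
  id <- .schema_fact_id(fact$schema_key)
  tr <- list(
    triple(id, "a", "FeatureSelectionFact"),
    triple(id, "hasSchema",
           lit(as.character(jsonlite::toJSON(fact$schema_key)))),
    triple(id, "hasSelected",
           lit(as.character(jsonlite::toJSON(fact$selected_features)))),
    triple(id, "hasSourcePolicy", fact$source_policy))
  if (is.finite(fact$metric)) {
    tr <- c(tr, list(triple(id, "hasMetric", lit(fact$metric))))
  }
  ks_add_triples(space, "world", do.call(rbind, tr))
}

#' Look up a stored feature subset for a dataset signature
#'
#' Reuse fires only on exact, order-sensitive column-name equality between
#' the signature and a recorded schema; any perturbation returns
#' \code{NULL}.
#'
#' @param space A knowledge space.
#' @param signature A [dataset_signature()] (or a \code{task_context}'s
#'   \code{signature} element).
#' @return Character vector of selected features, or \code{NULL}.
#' @export
reuse_features <- function(space, signature) {
  df <- space$partitions$world
  id <- .schema_fact_id(signature$column_names)
  if (!any(df$s == id & df$p == "a" & df$o == "FeatureSelectionFact")) {
    return(NULL)
  }
  schema <- as.character(jsonlite::fromJSON(.node_field(df, id, "hasSchema")))
  if (!identical(schema, as.character(signature$column_names))) return(NULL)
  as.character(jsonlite::fromJSON(.node_field(df, id, "hasSelected")))
}

#' Construct an answer fact
#' @param topic Topic text.
#' @param answer Answer text.
#' @param human_reward Numeric reward reported by a human.
#' @export
answer_fact <- function(topic, answer, human_reward = 0) {
  stopifnot(is.character(topic), nzchar(topic), is.character(answer))
  structure(list(topic = topic, answer = answer,
                 human_reward = as.numeric(human_reward)),
            class = "answer_fact")
}

#' Construct an image-vector fact
#' @param vector Numeric vector (e.g. an image embedding).
#' @param label Classification label.
#' @export
image_vector_fact <- function(vector, label) {
  stopifnot(is.numeric(vector), length(vector) >= 1L,
            is.character(label), nzchar(label))
  structure(list(vector = as.numeric(vector), label = label),
            class = "image_vector_fact")
}

#' Store an answer or image-vector fact
#' @param space A knowledge space.
#' @param fact An [answer_fact()] or [image_vector_fact()].
#' @return The updated space.
#' @export
store_fact <- function(space, fact) {
  if (inherits(fact, "answer_fact")) {
    id <- .schema_fact_id(c("answer", fact$topic))
    tr <- list(triple(id, "a", "AnswerFact"),
               triple(id, "hasTopic", lit(fact$topic)),
               triple(id, "hasAnswer", lit(fact$answer)),
               triple(id, "hasHumanReward", lit(fact$human_reward)))
  } else if (inherits(fact, "image_vector_fact")) {
    id <- .schema_fact_id(c("image", fact$label))
    tr <- list(triple(id, "a", "ImageVectorFact"),
               triple(id, "hasLabel", lit(fact$label)),
               triple(id, "hasVector",
                      lit(paste0("[", paste(sprintf("%.17g", fact$vector),
                                            collapse = ","), "]"))))
  } else {
    stop("unsupported fact type", call. = FALSE)
  }
  ks_add_triples(space, "world", do.call(rbind, tr))
}

#' Retrieve a stored answer fact by topic
#' @param space A knowledge space.
#' @param topic Topic text.
#' @return An [answer_fact()], or \code{NULL}.
#' @export
get_answer_fact <- function(space, topic) {
  df <- space$partitions$world
  id <- .schema_fact_id(c("answer", topic))
  if (!any(df$s == id & df$p == "a" & df$o == "AnswerFact")) return(NULL)
  answer_fact(.node_field(df, id, "hasTopic"),
              .node_field(df, id, "hasAnswer"),
              as.numeric(.node_field(df, id, "hasHumanReward")))
}

#' Retrieve a stored image-vector fact by label
#' @param space A knowledge space.
#' @param label Classification label.
#' @return An [image_vector_fact()], or \code{NULL}.
#' @export
get_image_fact <- function(space, label) {
  df <- space$partitions$world
  id <- .schema_fact_id(c("image", label))
  if (!any(df$s == id & df$p == "a" & df$o == "ImageVectorFact")) return(NULL)
  image_vector_fact(
    as.numeric(jsonlite::fromJSON(.node_field(df, id, "hasVector"))),
    .node_field(df, id, "hasLabel"))
}
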