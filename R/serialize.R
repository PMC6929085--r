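#' Save a trained model as JSON
#'
#' Serializes network, clustering and evaluation models to a JSON
#' document with an embedded type and format-version field; weight and
#' covariance matrices are stored row-major at full double precision.
#'
#' @param model an `ann_model`, `fcm_model`, `two_stage_model` or
#'   `posture_bayes_net`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
save_model <- function(model, path) {
  doc <- if (inherits(model, "ann_model")) {
    list(type = "ann_model", sizes = model$sizes,
         W2 = model$W2, W3 = model$W3, meta = model$meta)
  } else if (inherits(model, "fcm_model")) {
    list(type = "fcm_model", K2 = model$K2, b = model$b,
         centers = model$centers, labels = model$labels,
         category = model$category)
  } else if (inherits(model, "two_stage_model")) {
    list(type = "two_stage_model",
         ann = list(sizes = model$ann$sizes, W2 = model$ann$W2,
                    W3 = model$ann$W3, meta = model$ann$meta),
         fcm = lapply(model$fcm, function(m)
           list(K2 = m$K2, b = m$b, centers = m$centers,
                labels = m$labels, category = m$category)),
         category_map = as.list(model$category_map))
  } else if (inherits(model, "posture_bayes_net")) {
    list(type = "posture_bayes_net", posture = model$posture,
         ridge = model$ridge, m = model$m,
         head_parent = unname(model$topology$parent[["head"]]),
         edges = lapply(model$edges, function(e)
           list(mu = e$mu, Sigma = e$Sigma, ridge = e$ridge, m = e$m)),
         root = list(mu = model$root$mu, Sigma = model$root$Sigma))
  } else stop("unsupported model class: ", paste(class(model), collapse = "/"))
  doc$format_version <- 1L
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON file path.
#' @return the reconstructed model object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  rebuild_fcm <- function(d)
    structure(list(K2 = as.integer(d$K2), b = d$b,
                   centers = as.matrix(d$centers),
                   U = NULL, objective = NULL,
                   labels = if (is.null(d$labels)) NULL else as.integer(d$labels),
                   category = d$category),
              class = "fcm_model")
  rebuild_ann <- function(d)
    structure(list(sizes = as.integer(d$sizes), W2 = as.matrix(d$W2),
                   W3 = as.matrix(d$W3), meta = d$meta),
              class = "ann_model")
  switch(doc$type,
         ann_model = rebuild_ann(doc),
         fcm_model = rebuild_fcm(doc),
         two_stage_model = {
           cm <- unlist(doc$category_map)
           storage.mode(cm) <- "integer"
           structure(list(ann = rebuild_ann(doc$ann),
                          fcm = lapply(doc$fcm, rebuild_fcm),
                          category_map = cm),
                     class = "two_stage_model")
         },
         posture_bayes_net = {
           topo <- body_topology(head_parent = doc$head_parent)
           edges <- lapply(doc$edges, function(e) {
             mu <- as.numeric(e$mu)
             Sigma <- as.matrix(e$Sigma)
             P <- solve(Sigma + diag(e$ridge, 8L))
             structure(list(mu_s = mu[1:4], mu_t = mu[5:8], mu = mu,
                            Sigma = Sigma, ridge = e$ridge,
                            B11 = P[1:4, 1:4], B12 = P[1:4, 5:8],
                            B21 = P[5:8, 1:4], B22 = P[5:8, 5:8],
                            m = e$m), class = "edge_gaussian")
           })
           structure(list(posture = doc$posture, topology = topo,
                          ridge = doc$ridge, edges = edges,
                          root = structure(list(mu = as.numeric(doc$root$mu),
                                                Sigma = as.matrix(doc$root$Sigma)),
                                           class = "cond_gaussian"),
                          m = doc$m),
                     class = "posture_bayes_net")
         },
         stop("unknown model type in ", path, ": ", doc$type))
}
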