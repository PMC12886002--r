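# YAML configuration: one file with optional blocks `phantom:`,
# `preprocess:`, `enhancement:`, `model:`, `train:`, each holding arguments
# for the matching *_config() constructor.

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level blocks (`phantom`, `preprocess`,
#' `enhancement`, `model`, `train`) carry arguments for
#' [phantom_config()], [preprocess_config()], [enhancement_config()],
#' [model_config()] and [train_config()]. Missing blocks get the
#' constructor defaults; unknown argument names are rejected.
#'
#' @param path YAML file path.
#' @return Named list of the five config objects.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(block, ctor) {
    args <- raw[[block]] %||% list()
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      stop("unknown ", block, " option(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    # YAML reads vectors as lists; flatten scalars-only lists
    args <- lapply(args, function(a) if (is.list(a)) unlist(a) else a)
    do.call(ctor, args)
  }
  list(phantom = build("phantom", phantom_config),
       preprocess = build("preprocess", preprocess_config),
       enhancement = build("enhancement", enhancement_config),
       model = build("model", model_config),
       train = build("train", train_config))
}
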