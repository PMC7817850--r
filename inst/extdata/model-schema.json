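{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "actinf generative model spec",
  "description": "Discrete-state generative model for active inference. Matrices are nested lists of rows; every column of A, B[a] and E is a categorical distribution. Action and outcome indices are 1-based.",
  "type": "object",
  "required": ["n_states", "n_outcomes", "n_actions", "horizon", "A", "B", "D", "C", "policies"],
  "properties": {
    "n_states": { "type": "integer", "minimum": 1 },
    "n_outcomes": { "type": "integer", "minimum": 1 },
    "n_actions": { "type": "integer", "minimum": 1 },
    "horizon": { "type": "integer", "minimum": 1 },
    "A": {
      "description": "Likelihood P(o|s), row-major [outcome][state].",
      "type": "array",
      "items": { "type": "array", "items": { "type": "number", "minimum": 0 } }
    },
    "B": {
      "description": "One transition matrix per action, each row-major [next_state][prev_state].",
      "type": "array",
      "items": {
        "type": "array",
        "items": { "type": "array", "items": { "type": "number", "minimum": 0 } }
      }
    },
    "D": {
      "description": "Initial state prior.",
      "type": "array",
      "items": { "type": "number", "minimum": 0 }
    },
    "C": {
      "description": "Outcome preferences: either the log of a proper distribution per future time step, or raw utilities (normalized by log-softmax on load). A list over time steps of vectors over outcomes.",
      "type": "object",
      "oneOf": [
        { "required": ["log_probs"] },
        { "required": ["utilities"] }
      ],
      "properties": {
        "log_probs": { "type": "array", "items": { "type": "array", "items": { "type": "number" } } },
        "utilities": { "type": "array", "items": { "type": "array", "items": { "type": "number" } } }
      }
    },
    "E": {
      "description": "Optional deontic matrix P(o|policy), row-major [outcome][policy].",
      "type": "array",
      "items": { "type": "array", "items": { "type": "number", "minimum": 0 } }
    },
    "E_counts": {
      "description": "Optional non-negative concentration counts; E must equal their column normalization.",
      "type": "array",
      "items": { "type": "array", "items": { "type": "number", "minimum": 0 } }
    },
    "policies": {
      "description": "One list of 1-based action indices per policy; each of length horizon.",
      "type": "array",
      "minItems": 1,
      "items": { "type": "array", "items": { "type": "integer", "minimum": 1 } }
    },
    "gamma": { "type": "number", "exclusiveMinimum": 0, "default": 1 }
  }
}
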