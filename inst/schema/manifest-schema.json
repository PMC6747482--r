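{
  "title": "ssefold task manifest",
  "type": "object",
  "required": ["task", "sequence", "seed", "nPredictions", "models", "restraints"],
  "properties": {
    "task": {"type": "string"},
    "sequence": {"type": "string"},
    "structure": {"type": "string"},
    "seed": {"type": "number"},
    "nPredictions": {"type": "integer"},
    "samplingSteps": {"type": "integer"},
    "models": {"type": "array"},
    "scores": {"type": "array"},
    "clusterSizes": {"type": "array"},
    "restraints": {"type": "object"},
    "provenance": {"type": "array"}
  }
}
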