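{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "evinet viewer document",
  "type": "object",
  "required": ["format", "version", "elements"],
  "properties": {
    "format": {"type": "string", "enum": ["cytoscape-js"]},
    "version": {"type": "integer", "minimum": 1},
    "elements": {
      "type": "object",
      "required": ["nodes", "edges"],
      "properties": {
        "nodes": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["data"],
            "properties": {
              "data": {
                "type": "object",
                "required": ["id", "kind", "label", "role"],
                "properties": {
                  "id": {"type": "string"},
                  "kind": {"type": "string", "enum": ["protein", "chemical"]},
                  "label": {"type": "string"},
                  "role": {
                    "type": "string",
                    "enum": ["source", "target", "intermediate", "isolated",
                             "neighbor-sensitive", "neighbor-non-sensitive"]
                  }
                }
              }
            }
          }
        },
        "edges": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["data"],
            "properties": {
              "data": {
                "type": "object",
                "required": ["id", "source", "target", "score", "opacity",
                             "evidence", "link"],
                "properties": {
                  "id": {"type": "string"},
                  "source": {"type": "string"},
                  "target": {"type": "string"},
                  "score": {"type": "number", "minimum": 0, "maximum": 1},
                  "opacity": {"type": "number", "minimum": 0.1, "maximum": 1},
                  "evidence": {"type": "string"},
                  "link": {"type": "string"}
                }
              }
            }
          }
        }
      }
    }
  }
}
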