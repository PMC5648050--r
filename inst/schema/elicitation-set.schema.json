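{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ElicitationSet",
  "description": "A set of expert elicitation responses about the QoL of trial non-responders, on the EQ-5D utility scale multiplied by 100 (bounds -20..100), plus the observed-responder anchor scores shown during elicitation.",
  "type": "object",
  "required": ["responses"],
  "properties": {
    "schema_version": { "type": "string" },
    "anchors": {
      "type": "object",
      "required": ["open_observed", "evar_observed"],
      "properties": {
        "open_observed": { "type": "number", "minimum": -20, "maximum": 100 },
        "evar_observed": { "type": "number", "minimum": -20, "maximum": 100 }
      }
    },
    "responses": {
      "type": "array",
      "items": { "$ref": "#/$defs/expert_response" }
    }
  },
  "$defs": {
    "elicited_normal": {
      "type": "object",
      "required": ["mode", "sd"],
      "properties": {
        "mode": { "type": "number", "minimum": -20, "maximum": 100 },
        "sd": { "type": "number", "exclusiveMinimum": 0 }
      }
    },
    "expert_response": {
      "type": "object",
      "required": ["expert_id", "role", "open_missing", "evar_missing", "evar_given_open"],
      "properties": {
        "expert_id": { "type": "string", "minLength": 1 },
        "role": { "enum": ["doctor", "nurse", "other"] },
        "venue": { "enum": ["email", "conference", "face_to_face"] },
        "years_band": { "enum": ["2-3", "4-6", "7-10", ">10", "unknown"] },
        "familiarity": { "enum": ["some", "read_paper", "unknown"] },
        "correlation_category": { "enum": ["positive", "zero", "negative"] },
        "complete": { "type": "boolean" },
        "open_missing": { "$ref": "#/$defs/elicited_normal" },
        "evar_missing": { "$ref": "#/$defs/elicited_normal" },
        "evar_given_open": {
          "type": "object",
          "required": ["conditioning_value", "distribution"],
          "properties": {
            "conditioning_value": { "type": "number", "minimum": -20, "maximum": 100 },
            "distribution": { "$ref": "#/$defs/elicited_normal" }
          }
        }
      }
    }
  }
}
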