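{
  "_comment": "Synthetic default ICBS item -> meta-behaviour map. The item codes are artifact-defined stand-ins for the published coding grid (not reproduced here); edit or replace this file to match a real coding configuration. Meta-behaviour labels are the five caregiver and six infant analysis-level categories.",
  "caregiver": {
    "CG_VOC": "Vocal solicitation",
    "CG_NAME_CALL": "Vocal solicitation",
    "CG_TOUCH": "Touching",
    "CG_TICKLE": "Touching",
    "CG_GEST": "Gestural solicitation",
    "CG_SHOW_OBJ": "Gestural solicitation",
    "CG_REGUP": "Regulation up",
    "CG_REGDOWN": "Regulation down"
  },
  "infant": {
    "INF_OBJ_MANIP": "Behavior with object",
    "INF_OBJ_LOOK": "Behavior with object",
    "INF_VOCAL": "Vocalizations/Expressive",
    "INF_BABBLE": "Vocalizations/Expressive",
    "INF_JOINT_ATT": "Inter-subjective",
    "INF_IMITATE": "Inter-subjective",
    "INF_SEEK_PERS": "Seeking people/Active",
    "INF_REACH_PERS": "Seeking people/Active",
    "INF_LOOK_PERS": "Receptive",
    "INF_SMILE_PERS": "Receptive",
    "INF_ORIENT": "Orienting/Exploratory",
    "INF_EXPLORE": "Orienting/Exploratory"
  }
}
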