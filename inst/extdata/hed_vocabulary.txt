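# Trimmed HED 2.0 vocabulary snapshot shipped with esskit.
# One node per line; leading tab count = depth; attribute flags in brackets.
version: 2.0
Event
	Category
		Experimental stimulus
		Participant response
		Experiment control
		Miscellaneous
	Label [takesValue]
	Description [takesValue]
	Duration [takesValue]
Sensory Presentation
	Auditory
		Ding
		Buzz
		Tone [extensionAllowed]
		Speech [extensionAllowed]
	Visual [extensionAllowed]
	Tactile [extensionAllowed]
Participant
	ID [takesValue]
	Effect
		Auditory [extensionAllowed]
		Visual [extensionAllowed]
		Tactile [extensionAllowed]
		Cognitive
			Expected
			Oddball
				Target
				Novel
			Meaningful [extensionAllowed]
			Memory [extensionAllowed]
		State [extensionAllowed]
	Role [extensionAllowed]
Action
	Button press [extensionAllowed]
	Button release
	Eye blink
	Movement [extensionAllowed]
Attribute
	Onset
	Offset
	Repetition [takesValue]
	Direction [extensionAllowed]
	Location [extensionAllowed]
	Intensity [takesValue]
Item
	Object [extensionAllowed]
	Sound [extensionAllowed]
Paradigm [extensionAllowed]
Time-Locked Event [extensionAllowed]
Custom [extensionAllowed]
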