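# Freely moving Go/No-go luminance discrimination task
task_kind = "gonogo_freely_moving"
iti = 0.5
reward_volume_ul = 4.0
response_delay = 0.5
stimulus_duration = 4.0

[session_end]
max_rewards = 190
max_duration_min = 120

[schedule]
n_trials = 2000
labels = ["go", "nogo"]
probs = [0.3, 0.7]
max_consecutive = 10
seed = 1

[epochs.prestim]
order = 1
name = "Prestim"
trigger = "event"
value = "init_touch"
stimulus = "gray"

[epochs.decision]
order = 2
name = "Decision"
trigger = "timer"
value = 4.0
stimulus = "per_trial"

[contingency.go]
correct_side = "center"
reward_port = "center"
volume_ul = 4.0

[contingency.nogo]
correct_side = "none"
reward_port = "none"
volume_ul = 4.0
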