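{
  "schema_id": "ffq_full_v1",
  "version": "full",
  "items": [
    {"item_id": "fresh_fruit", "food_group_id": "fruits", "label": "Fresh fruit", "representative_foods": ["apple", "orange", "banana", "seasonal fruit"], "portion_description": "1 piece or 1 cup chopped"},
    {"item_id": "salad_raw_veg", "food_group_id": "vegetables", "label": "Salads and raw vegetables", "representative_foods": ["mixed salad", "tomato", "carrot sticks"], "portion_description": "1 bowl or 1 cup"},
    {"item_id": "cooked_veg", "food_group_id": "vegetables", "label": "Cooked vegetables", "representative_foods": ["greens", "ratatouille", "vegetable soup"], "portion_description": "1 plate or side serving"},
    {"item_id": "pulses_legumes", "food_group_id": "pulses", "label": "Pulses and legumes", "representative_foods": ["chickpeas", "lentils", "beans"], "portion_description": "1 plate cooked (about 150 g)"},
    {"item_id": "nuts_unsalted", "food_group_id": "nuts", "label": "Unsalted natural nuts", "representative_foods": ["walnuts", "almonds", "hazelnuts", "pistachios"], "portion_description": "1 handful (about 30 g)"},
    {"item_id": "water_glasses", "food_group_id": "water", "label": "Water", "representative_foods": ["tap water", "bottled water", "sparkling water"], "portion_description": "1 glass (about 250 mL)"},
    {"item_id": "wholegrain_bread", "food_group_id": "wholegrains", "label": "Wholegrain bread", "representative_foods": ["wholemeal loaf", "wholegrain toast"], "portion_description": "2 slices or 1 roll"},
    {"item_id": "wholegrain_pasta_rice", "food_group_id": "wholegrains", "label": "Wholegrain pasta, rice and cereals", "representative_foods": ["brown rice", "wholewheat pasta", "oats"], "portion_description": "1 plate cooked"},
    {"item_id": "olive_oil_dressing", "food_group_id": "olive_oil", "label": "Virgin olive oil as dressing", "representative_foods": ["oil on salad", "oil on bread"], "portion_description": "1 tablespoon"},
    {"item_id": "olive_oil_cooking", "food_group_id": "olive_oil", "label": "Virgin olive oil for cooking", "representative_foods": ["sauteing", "roasting"], "portion_description": "1 tablespoon"},
    {"item_id": "white_fish", "food_group_id": "fish", "label": "White fish", "representative_foods": ["hake", "cod", "sea bass"], "portion_description": "1 fillet (about 125 g)"},
    {"item_id": "oily_fish", "food_group_id": "fish", "label": "Oily fish and seafood", "representative_foods": ["sardines", "salmon", "mackerel", "mussels"], "portion_description": "1 serving (about 125 g)"},
    {"item_id": "salted_snacks", "food_group_id": "salt", "label": "Salty snacks", "representative_foods": ["crisps", "salted crackers", "salted nuts"], "portion_description": "1 small bag or bowl"},
    {"item_id": "added_salt_meals", "food_group_id": "salt", "label": "Salt added at the table", "representative_foods": ["salt on cooked dishes"], "portion_description": "meals with added salt"},
    {"item_id": "sugary_drinks", "food_group_id": "sugary_foods", "label": "Sugary drinks", "representative_foods": ["soft drinks", "sweetened juices", "sweetened coffee"], "portion_description": "1 glass or can"},
    {"item_id": "sweets_pastries", "food_group_id": "sugary_foods", "label": "Sweets and pastries", "representative_foods": ["biscuits", "pastries", "chocolate", "dessert"], "portion_description": "1 piece or serving"},
    {"item_id": "red_meat_dishes", "food_group_id": "red_meat", "label": "Red meat", "representative_foods": ["beef", "pork", "lamb"], "portion_description": "1 serving (about 125 g)"},
    {"item_id": "cold_meats", "food_group_id": "processed_meat", "label": "Cold meats in sandwiches and snacks", "representative_foods": ["ham", "salami", "mortadella"], "portion_description": "1 sandwich filling or 3-4 slices"},
    {"item_id": "sausages_cured", "food_group_id": "processed_meat", "label": "Sausages and cured meats", "representative_foods": ["sausages", "bacon", "chorizo"], "portion_description": "1 serving (about 100 g)"},
    {"item_id": "ultraprocessed_meals", "food_group_id": "ultraprocessed", "label": "Ultra-processed and ready meals", "representative_foods": ["pizza", "instant noodles", "packaged snacks", "fast food"], "portion_description": "1 dish or menu"}
  ],
  "short_items": [
    "fresh_fruit", "salad_raw_veg", "pulses_legumes", "nuts_unsalted",
    "water_glasses", "wholegrain_bread", "olive_oil_dressing", "white_fish",
    "salted_snacks", "sugary_drinks", "red_meat_dishes", "cold_meats",
    "ultraprocessed_meals"
  ]
}
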